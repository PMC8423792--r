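---
title: "Replicating health studies under federated learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicating health studies under federated learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedstudy)
```

## The question the package answers

A health study's conclusions are its effect estimates — odds ratios, risk
ratios, regression coefficients with confidence intervals — and, for
prediction tasks, its discrimination (AUC). `fedstudy` simulates analysing
the same cohort two ways: classically, with all rows pooled on one server,
and federatedly, where rows stay with their owners (a single patient's
device at one extreme, a hospital or country silo at the other) and only
model updates are aggregated. Because every cohort is synthetic with known
generating coefficients, each comparison has a ground truth: we can ask not
only whether the two regimes agree with each other, but whether both
recover the truth at nominal coverage.

## Models and training objective

Both regimes minimize the identical objective: the mean per-example
Bernoulli negative log-likelihood plus `l1 * sum(|w|) + l2 * sum(w^2)`
over penalized parameter blocks. Two model families share a flat
parameter-vector interface so the engine is model-agnostic:

* **Binomial GLMs.** Logit link (coefficients are log odds ratios) or log
  link (log risk ratios, the endpoint of the cluster-randomized trial
  design). The log link needs a safeguard: `exp(eta) > 1` is not a
  probability, so the linear predictor is clamped at 0 inside the
  likelihood, the gradient is flattened on the clamped region, and clamped
  rows are counted in the training trace. A log-link model initialized at
  `beta = 0` would start exactly on that clamp (fitted probability 1), so
  the engine initializes the intercept at the log empirical prevalence of
  the training split; slopes start at zero, and logit models start at zero
  entirely.
* **Embedding feed-forward network.** For cohorts where each patient is a
  multiset of discrete tokens (an EHR-notes abstraction): an embedding
  table pooled over the patient's tokens (sum or mean), dense hidden
  layers (ReLU or tanh), a sigmoid output. With `vocab_size = 0` the same
  machinery is a plain MLP on tabular covariates. Gradients are analytic
  backpropagation, verified against central finite differences to 1e-6 in
  the test suite.

Penalties never touch intercepts or biases (standard practice), and the L1
subgradient at 0 is taken as 0, keeping updates deterministic.

## Federated averaging and its centralized anchor

Each server round samples `m` clients uniformly — with replacement by
default, a drawn-twice client contributing twice — runs each client's
local optimizer (`local_epochs` passes of seeded minibatch SGD or Adam)
from the current global parameters, and applies the example-count-weighted
mean of the client deltas, scaled by `server_lr`.

The design anchor is an exact identity: with full participation, one
full-batch local step, and `server_lr = 1`, the weighted average of client
gradients is algebraically the pooled gradient, so federated averaging
*is* centralized gradient descent, round by round. The suite asserts this
lock-step equivalence to 1e-10 for both links, with and without penalties.
Every divergence between regimes therefore comes from the things the
framework varies deliberately: client subsampling, multiple local steps,
non-IID partitions, and privacy noise.

GLM client defaults are one local epoch at full batch — chosen to maximize
comparability with the centralized fit; the EHR network uses local Adam
(learning rate 0.01, minibatch 16), the configuration of the cross-device
EHR experiment it emulates. For GLM clients taking a single full-batch SGD
step the engine uses a vectorized path (per-client gradients via grouped
row sums) that is algebraically identical to the per-client loop; the
suite asserts equality to 1e-13 including under both DP modes. This is
what makes full-participation training over ~10^4 single-patient clients
run in seconds.

## Units of federation

`partition_per_patient()` is the cross-device extreme. Natural silos come
from a grouping column (country, community, hospital unit). Random silos
use a Dirichlet construction: proportions `p ~ Dirichlet(alpha * 1_G)`,
then each patient independently joins silo `g` with probability `p_g`.
The construction is the standard one for heterogeneous federated
benchmarks; small `alpha` gives highly unequal silos, and the marginal
size of a silo is Beta-Binomial, which the tests verify by chi-square
goodness of fit. Empty silos are dropped rather than resampled — the
sampling law stays exact, at the cost that the realized silo count may be
below `G`. Users wanting quota-based equal silos can compare against
`alpha -> Inf`.

## Differential privacy

Central DP clips each client delta to L2 norm `S` and adds
`N(0, (zS/m)^2)` per-coordinate noise to the *uniform* mean of the `m`
contributions. The uniform (not size-weighted) mean is deliberate: it is
what bounds the sensitivity of the aggregate at `S/m`, and it is the one
place federated aggregation deviates from weighted averaging (with
per-patient clients the two coincide anyway). Local DP clips and noises
each upload at sd `z*S`; its per-round epsilon is reported via the
classical analytic Gaussian bound `epsilon = sqrt(2 log(1.25/delta))/z`,
and a cumulative figure additionally via basic composition — a
deliberately conservative caveat, since the headline local guarantee is
per round.

Central accounting composes Renyi-DP of the Poisson-subsampled Gaussian:
the binomial-expansion bound at integer orders 2..64 plus a log-spaced
integer grid to 512, converted to `(epsilon, delta)` by minimizing
`T * RDP(alpha) + log(1/delta)/(alpha - 1)` over orders. At `q = 1` the
bound reduces exactly to `alpha/(2 z^2)`, and the suite checks agreement
with the single-round closed form within 10%, monotonicity in `T`, `q`,
and `1/z`, and the square-root-like growth in `T` while the per-round
budget is small. One consequence of the finite order grid: as `z` grows,
epsilon floors at about `log(1/delta)/(alpha_max - 1)` (~0.02 at
`delta = 1e-5`) instead of reaching 0.

A practical finding reproduced in the acceptance tests: on the small
(n = 299) cohort, the utility cost of central DP is dominated by the
clipping bias, not the noise — clipped steps shrink each round's progress,
so the DP arm needs more rounds, after which a strong budget
(`S = 0.5`, `z = 10`, 150 rounds, epsilon about 6.6 at `delta = 1e-5`)
costs under 0.03 AUC. AUC is insensitive to a global rescaling of
coefficients, which is why direction-preserving clipping is relatively
benign for discrimination even when it slows likelihood convergence.

## Inference from additive sufficient statistics

Standard errors use the unpenalized expected Fisher information
`I(beta) = sum_i w_i x_i x_i'` (IRLS weights `mu(1-mu)` for logit,
`mu/(1-mu)` for log) evaluated at the estimate — also when the estimate
came from a penalized fit, with the penalty magnitudes recorded in the
report. The information is a sum over rows, so per-client partial sums
equal the pooled matrix exactly (asserted to 1e-12): federated inference
is not an approximation of centralized inference but the same computation
re-bracketed. The cluster-robust sandwich uses per-cluster summed scores;
those sums are additive across silos whenever silo boundaries respect
clusters, the natural deployment (a community's rows live in one silo).
With every row its own cluster the estimator reduces to HC0, which the
tests verify against the `sandwich` package. p-values are two-sided Wald
with no multiplicity correction, matching how the replicated designs
report per-variable CIs; intervals are reported on the ratio scale.

AUC is the Mann-Whitney statistic with half-credit ties, computed from
midranks and verified against brute-force all-pairs counting. Its
uncertainty is summarized by percentile intervals over repeated
re-randomized stratified 80/20 splits — the 100-execution protocol of the
replicated studies — rather than DeLong's variance, for protocol fidelity.

## What the generators emulate, and what they do not

The synthetic cohorts reproduce the *statistical shape* of the replicated
studies — sample sizes (299, 768, 1712, 9275 and so on), covariate counts,
link functions, cluster structure, token-sequence labels — with known
coefficients chosen to give realistic effect sizes (odds ratios between
roughly 0.35 and 4) and outcome prevalences (10–30%). The original
studies' covariate distributions are not published as generative models,
so marginals default to standard normal / Bernoulli / categorical forms
chosen for testability. Passing tests therefore demonstrate correctness of
the machinery and calibration under the generating model, not fidelity to
any real dataset: real cohorts bring measurement error, missingness,
confounding, and covariate dependence the generators deliberately omit.
The EHR generator likewise produces bag-of-token patients with a
latent-topic label model — enough structure for an embedding classifier to
have signal to find — without imitating real medical-record schemas, and
no attempt is made to reproduce the original 17.5-million-parameter
vocabulary, which is unspecified; `count_params()` reports the size of any
configured network instead.

One subtlety the cluster-trial generator surfaced: the familiar
latent-scale intraclass correlation `sigma_u^2/(sigma_u^2 + pi^2/3)` is
*not* what an ANOVA on binary outcomes estimates. The observed-scale ICC
is attenuated (0.172 vs 0.233 at `sigma_u = 1`, prevalence 0.5); the tests
pin the ANOVA estimate to the exact observed-scale value obtained by
numerically integrating the generating model over the random effect.

## Numerical and design choices

* **Reproducibility.** Every generator and the engine draw from an
  isolated RNG stream seeded once per object; sub-seeds derive via a
  Lehmer step. Identical configs reproduce cohorts, traces, and reports
  bit for bit; the user's session RNG is never disturbed.
* **Splits.** Stratified by outcome; the evaluation holdout defaults to
  20% per the replicated protocol and is re-randomized per execution in
  `repeated_split_evaluate()`. A split that loses an outcome class is
  redrawn and counted.
* **Degenerate inputs.** Zero-variance features are reported as
  non-identifiable; a singular information matrix falls back to a flagged
  pseudo-inverse; log-link specs whose realized probabilities exceed 1 are
  rejected with a diagnostic naming the offending covariate; a round in
  which every sampled client fails aborts with its trace.
* **Problem sizes in the tests.** The suite runs the study-scale
  configurations it emulates (n = 299 with 12 covariates, n = 1712
  community trial, n = 9275 registry with per-patient federation) and
  scales Monte-Carlo layers (seed counts, repeated splits, goodness-of-fit
  replicates) to desk size; each file states its sizes inline.

## Known limitations

Simulation only: no transport layer, no asynchronous or dropped-out
clients beyond sampling, no secure-aggregation masking. Server-side
momentum optimizers are out of scope (`server_lr` is plain). Local-DP
cumulative spend uses basic composition, which is loose. The accountant's
finite order grid floors epsilon for very large noise multipliers. And the
agreement machinery flags CI overlap and same-conclusion status; it is not
a formal equivalence test between regimes.
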