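# Shared fixture builders: small cohorts with the statistical shape of the
# replicated studies, generated in code at test time.

# Heart-failure-like cohort: n = 299, 12 covariates, logistic outcome.
hf_spec <- function(seed = 1L, n = 299L) {
  covs <- c(
    lapply(paste0("c", 1:7), covariate_spec, kind = "continuous"),
    lapply(paste0("b", 1:5), covariate_spec, kind = "binary", prevalence = 0.4)
  )
  beta <- c(-1.2, 0.8, -0.6, 0.4, 0.3, -0.3, 0.2, -0.2, 0.5, -0.5, 0.4, -0.4, 0.3)
  cohort_spec(n, covs, beta, link = "logit", seed = seed)
}

# SARS-CoV-2-registry-like cohort: n = 9275, 3 covariates
# (age, sex, recent cancer history) with nonzero effects.
sars_spec <- function(seed = 1L, n = 9275L) {
  cohort_spec(
    n,
    list(covariate_spec("age", "continuous"),
         covariate_spec("female", "binary", prevalence = 0.5),
         covariate_spec("cancer", "binary", prevalence = 0.05)),
    beta = c(-2, 1.39, -1.05, 0.63), link = "logit", seed = seed)
}

# Minimal 2-covariate logistic cohort for engine tests.
small_spec <- function(seed = 1L, n = 300L) {
  cohort_spec(
    n,
    list(covariate_spec("x1", "continuous"),
         covariate_spec("x2", "binary", prevalence = 0.5)),
    beta = c(-0.5, 0.4, 0.3), link = "logit", seed = seed)
}

# Tiny EHR-like cohort for MLP tests.
tiny_ehr_spec <- function(seed = 1L, n = 120L, vocab = 30L) {
  ehr_cohort_spec(
    n, vocab,
    length_dist = list(dist = "poisson", lambda = 12),
    demographics = list(covariate_spec("age", "continuous")),
    label_model = list(intercept = -1, topic = c(2, -2), demo = 0.3),
    seed = seed)
}

tiny_mlp <- function(vocab = 30L) {
  mlp_spec(vocab, embedding_dim = 4L, hidden_sizes = c(6L, 4L),
           l1 = 1e-4, l2 = 0.01)
}

grad_fd <- function(params, batch, spec, h = 1e-6) {
  vapply(seq_along(params$values), function(i) {
    e <- numeric(length(params$values)); e[i] <- h
    up <- fedstudy:::new_params(params$values + e, params$registry)
    dn <- fedstudy:::new_params(params$values - e, params$registry)
    (as.numeric(local_loss(up, batch, spec)) -
       as.numeric(local_loss(dn, batch, spec))) / (2 * h)
  }, numeric(1))
}
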