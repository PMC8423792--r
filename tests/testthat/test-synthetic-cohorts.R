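test_that("cohort generation is deterministic and round-trips through CSV", {
  spec <- small_spec(seed = 42)
  a <- generate_tabular_cohort(spec)
  b <- generate_tabular_cohort(spec)
  expect_identical(a$data, b$data)

  tmp <- file.path(tempdir(), "coh")
  write_cohort(a, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$data$outcome, a$data$outcome)
  expect_equal(back$data$x1, a$data$x1, tolerance = 1e-12)
  expect_equal(back$spec$beta, spec$beta)
  expect_equal(back$spec$seed, spec$seed)
})

test_that("zero coefficients give symmetric outcomes", {
  spec <- cohort_spec(10000, list(covariate_spec("x", "continuous")),
                      beta = c(0, 0), seed = 5)
  coh <- generate_tabular_cohort(spec)
  expect_lt(abs(mean(coh$data$outcome) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a binary covariate's empirical log-OR matches the generating coefficient", {
  # logistic model with one binary covariate: the population 2x2 log-odds
  # ratio equals the coefficient exactly
  spec <- cohort_spec(200000, list(covariate_spec("x", "binary", prevalence = 0.5)),
                      beta = c(-1, 0.7), seed = 9)
  coh <- generate_tabular_cohort(spec)
  tab <- table(coh$data$x, coh$data$outcome) + 0  # double: avoid int overflow
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_lt(abs(lor - 0.7), 0.02)
})

test_that("log-link specs with impossible probabilities are rejected with a diagnostic", {
  bad <- cohort_spec(1000, list(covariate_spec("dose", "continuous", mean = 2)),
                     beta = c(-0.5, 1), link = "log", seed = 3)
  expect_error(generate_tabular_cohort(bad), "dose")
  # a safe log-link spec never emits a probability above 1
  ok <- cohort_spec(5000, list(covariate_spec("x", "binary", prevalence = 0.3)),
                    beta = c(-2, 0.5), link = "log", seed = 3)
  coh <- generate_tabular_cohort(ok)
  X <- fedstudy:::cohort_design(coh)
  eta <- -2 + X * 0.5
  expect_true(all(exp(eta) <= 1))
})

test_that("categorical covariates expand to reference-coded indicators", {
  cv <- covariate_spec("site", "categorical",
                       levels = c("A", "B", "C"), probs = c(0.5, 0.3, 0.2))
  spec <- cohort_spec(500, list(cv), beta = c(0, 0.5, -0.5), seed = 2)
  coh <- generate_tabular_cohort(spec)
  X <- fedstudy:::cohort_design(coh)
  expect_identical(colnames(X), c("siteB", "siteC"))
  # reference level A maps to the zero row
  expect_true(all(X[coh$data$site == "A", ] == 0))
  expect_true(all(rowSums(X) <= 1))
})

test_that("covariate and cohort specs validate their parameters", {
  expect_error(covariate_spec("x", "continuous", sd = 0), "sd")
  expect_error(covariate_spec("x", "binary", prevalence = 1.2), "prevalence")
  expect_error(covariate_spec("x", "categorical", levels = c("a", "b"),
                              probs = c(0.7, 0.7)), "sum to 1")
  expect_error(cohort_spec(10, list(covariate_spec("x", "binary")),
                           beta = c(0, 1, 2)), "length")
  expect_error(cohort_spec(5, list(covariate_spec("x", "binary")),
                           beta = c(0, 1), clusters = list(G = 10)), "exceeds")
})

test_that("cluster trials randomize treatment at the community level", {
  sp <- cohort_spec(1712, list(covariate_spec("treatment", "binary", prevalence = 0.5)),
                    beta = c(-2.2, -0.11), link = "log",
                    clusters = list(G = 30, sigma_u = 0.2,
                                    treatment_at_cluster = TRUE),
                    seed = 8)
  tr <- generate_cluster_trial(sp)
  d <- tr$data
  expect_equal(nrow(d), 1712)
  per_cluster <- tapply(d$treatment, d$cluster_id, function(v) length(unique(v)))
  expect_true(all(per_cluster == 1))
  expect_equal(length(unique(d$cluster_id)), 30)
  # both arms present
  expect_true(length(unique(tapply(d$treatment, d$cluster_id, max))) == 2)
})

anova_icc <- function(outcome, cluster) {
  a <- stats::anova(stats::aov(outcome ~ factor(cluster)))
  msb <- a[1, 3]; msw <- a[2, 3]
  counts <- table(cluster)
  n0 <- (sum(counts) - sum(counts^2) / sum(counts)) / (length(counts) - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

test_that("cluster random effects produce the predicted outcome correlation", {
  base <- list(covariate_spec("treatment", "binary", prevalence = 0.5))
  # no random effect: ICC indistinguishable from zero
  sp0 <- cohort_spec(50000, base, beta = c(0, 0.3), link = "logit",
                     clusters = list(G = 50, sigma_u = 0,
                                     treatment_at_cluster = TRUE), seed = 4)
  icc0 <- with(generate_cluster_trial(sp0)$data, anova_icc(outcome, cluster_id))
  expect_lt(abs(icc0), 0.01)

  # sigma_u = 1: ANOVA ICC matches the observed-scale value of the
  # generating model, computed by numerical integration over the random
  # effect (the latent-scale value sigma^2/(sigma^2 + pi^2/3) = 0.233 is
  # attenuated on the binary scale)
  sp1 <- cohort_spec(50000, base, beta = c(0, 0.3), link = "logit",
                     clusters = list(G = 50, sigma_u = 1,
                                     treatment_at_cluster = TRUE), seed = 4)
  icc1 <- with(generate_cluster_trial(sp1)$data, anova_icc(outcome, cluster_id))
  pg <- function(u) 0.5 * stats::plogis(u) + 0.5 * stats::plogis(u + 0.3)
  m1 <- stats::integrate(function(u) pg(u) * stats::dnorm(u), -8, 8)$value
  m2 <- stats::integrate(function(u) pg(u)^2 * stats::dnorm(u), -8, 8)$value
  icc_oracle <- (m2 - m1^2) / (m1 * (1 - m1))
  expect_lt(abs(icc1 - icc_oracle) / icc_oracle, 0.10)
  expect_lt(icc1, 1 / (1 + pi^2 / 3))  # observed-scale attenuation
})

test_that("maximum-likelihood refits recover the generating coefficients", {
  # centralized ML refit of the generating GLM: truth within 3 SEs
  hits <- 0L
  total <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    spec <- cohort_spec(
      100000,
      list(covariate_spec("x1", "continuous"),
           covariate_spec("x2", "binary", prevalence = 0.3)),
      beta = c(-1, 0.5, -0.7), seed = 1000 + s)
    coh <- generate_tabular_cohort(spec)
    X <- cbind(1, fedstudy:::cohort_design(coh))
    fit <- stats::glm.fit(X, coh$data$outcome, family = stats::binomial())
    se <- sqrt(diag(chol2inv(chol(crossprod(
      X * sqrt(fit$weights))))))
    ok <- abs(fit$coefficients - spec$beta) < 3 * se
    hits <- hits + sum(ok)
    total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("EHR cohorts are deterministic with controllable prevalence", {
  spec <- tiny_ehr_spec(seed = 3)
  a <- generate_ehr_cohort(spec)
  b <- generate_ehr_cohort(spec)
  expect_identical(a$data, b$data)
  expect_identical(a$tokens, b$tokens)

  # token matrix is consistent with per-patient counts
  M <- token_matrix(a)
  expect_equal(rowSums(M), a$data$n_tokens)
  expect_true(all(M >= 0))

  # degenerate vocabulary, label ignores tokens: prevalence = plogis(intercept)
  sp1 <- ehr_cohort_spec(4000, 1, label_model = list(intercept = qlogis(0.3),
                                                     topic = 0, demo = NULL),
                         seed = 6)
  coh1 <- generate_ehr_cohort(sp1)
  expect_lt(abs(mean(coh1$data$outcome) - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))

  # mortality-like prevalence parameterized to ~0.1 lands in the binomial
  # 99% band
  sp2 <- ehr_cohort_spec(2000, 500, label_model = list(intercept = qlogis(0.1),
                                                       topic = c(0, 0), demo = NULL),
                         seed = 7)
  coh2 <- generate_ehr_cohort(sp2)
  band <- stats::qnorm(0.995) * sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(mean(coh2$data$outcome) - 0.1), band)
})
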