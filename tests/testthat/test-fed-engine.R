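test_that("client sampling is uniform with the stated cohort sizes", {
  coh <- generate_tabular_cohort(hf_spec(seed = 5))
  part <- partition_per_patient(coh)

  # full participation without replacement returns the whole client pool
  full <- fedstudy:::with_seed(1, sample_clients(part, fraction = 1,
                                                 with_replacement = FALSE))
  expect_setequal(full, names(part$client_sizes))
  expect_equal(length(full), 299L)

  # the cross-device EHR setting: 16 participants per round
  s16 <- fedstudy:::with_seed(2, sample_clients(part, clients_per_round = 16))
  expect_equal(length(s16), 16L)
  expect_true(all(s16 %in% names(part$client_sizes)))

  # frequency of single draws from 5 equal clients: binomial 3-sigma band
  pool <- as.character(1:5)
  draws <- fedstudy:::with_seed(3, sample(pool, 1e5, replace = TRUE))
  freq <- table(factor(draws, levels = pool)) / 1e5
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / 1e5)))
})

test_that("aggregation is the exact example-count-weighted mean", {
  expect_equal(aggregate_updates(list(c(1, -2, 3)), 7), c(1, -2, 3))
  expect_equal(aggregate_updates(list(0, 4), c(1, 3)), 3)
  set.seed(9)
  deltas <- lapply(1:50, function(i) rnorm(8))
  w <- runif(50, 0.5, 20)
  oracle <- {
    acc <- numeric(8)
    for (i in 1:50) acc <- acc + w[i] * deltas[[i]]
    acc / sum(w)
  }
  expect_equal(aggregate_updates(deltas, w), oracle, tolerance = 1e-12)
  expect_error(aggregate_updates(list(1:2, 1:3), c(1, 1)), "length")
})

test_that("full-participation FedAvg tracks centralized gradient descent in lock-step", {
  for (link in c("logit", "log")) {
    spec <- if (link == "logit") {
      small_spec(seed = 6, n = 250L)
    } else {
      cohort_spec(250, list(covariate_spec("x1", "binary", prevalence = 0.4),
                            covariate_spec("x2", "binary", prevalence = 0.3)),
                  beta = c(-1.5, 0.3, -0.4), link = "log", seed = 6)
    }
    coh <- generate_tabular_cohort(spec)
    ms <- glm_spec(c("x1", "x2"), link = link, l1 = 0.001, l2 = 0.01)
    opt <- optimizer_config(learning_rate = 0.25)
    fed <- run_federated_training(
      coh, partition_per_patient(coh), ms,
      fed_config(rounds = 30, with_replacement = FALSE, optimizer = opt,
                 eval_split = 0, seed = 3))
    cen <- run_centralized_training(coh, ms, opt, max_iter = 30, tol = 0)
    expect_lt(max(abs(fed$params$values - cen$params$values)), 1e-10)
    expect_lt(max(abs(fed$trace$train_loss - cen$trace$train_loss)), 1e-10)
  }
})

test_that("the vectorized GLM path equals the per-client loop, with and without DP", {
  coh <- generate_tabular_cohort(small_spec(seed = 5, n = 300L))
  ms <- glm_spec(c("x1", "x2"), l1 = 0.001, l2 = 0.01)
  part <- partition_dirichlet(coh, G = 8, alpha = 5, seed = 2)
  cfg <- fed_config(rounds = 8, clients_per_round = 4,
                    optimizer = optimizer_config(learning_rate = 0.3),
                    eval_split = 0.2, seed = 13)
  configs <- list(
    NULL,
    dp_config("central", clip_norm = 0.05, noise_multiplier = 1,
              delta = 1e-3, seed = 4),
    dp_config("local", clip_norm = 0.05, noise_multiplier = 0.5,
              delta = 1e-3, seed = 4))
  for (dp in configs) {
    fast <- suppressWarnings(run_federated_training(coh, part, ms, cfg, dp = dp))
    slow <- suppressWarnings(run_federated_training(coh, part, ms, cfg, dp = dp,
                                                    .force_generic = TRUE))
    expect_lt(max(abs(fast$params$values - slow$params$values)), 1e-13)
  }
})

test_that("absent DP equals a zero-noise infinite-clip central configuration", {
  coh <- generate_tabular_cohort(small_spec(seed = 7, n = 200L))
  ms <- glm_spec(c("x1", "x2"))
  part <- partition_per_patient(coh)  # equal client sizes: uniform = weighted
  cfg <- fed_config(rounds = 10, clients_per_round = 40,
                    optimizer = optimizer_config(learning_rate = 0.4),
                    eval_split = 0, seed = 21)
  off <- run_federated_training(coh, part, ms, cfg)
  noop <- run_federated_training(coh, part, ms, cfg,
                                 dp = dp_config("central", clip_norm = 1e9,
                                                noise_multiplier = 0,
                                                delta = 1e-3))
  expect_equal(off$params$values, noop$params$values, tolerance = 1e-14)
})

test_that("training traces are complete and reproducible bit-for-bit", {
  coh <- generate_tabular_cohort(small_spec(seed = 8, n = 250L))
  ms <- glm_spec(c("x1", "x2"))
  part <- partition_dirichlet(coh, G = 6, alpha = 2, seed = 3)
  cfg <- fed_config(rounds = 12, clients_per_round = 3,
                    optimizer = optimizer_config(learning_rate = 0.3),
                    eval_split = 0.2, seed = 31)
  a <- run_federated_training(coh, part, ms, cfg)
  b <- run_federated_training(coh, part, ms, cfg)
  expect_equal(nrow(a$trace), 12L)
  expect_identical(a$trace$round, 1:12)
  expect_true(all(lengths(a$trace$clients) == 3L))
  expect_identical(a$trace, b$trace)
  expect_identical(a$params$values, b$params$values)
})

test_that("a round where every client fails aborts with a diagnostic", {
  coh <- generate_tabular_cohort(small_spec(seed = 9, n = 40L))
  ms <- glm_spec(c("x1", "x2"), l2 = 0.01)
  part <- partition_dirichlet(coh, G = 2, alpha = 5, seed = 1)
  # an absurd learning rate overflows the penalized gradient within one
  # client's minibatch pass, producing non-finite gradients for every client
  cfg <- fed_config(rounds = 2, optimizer = optimizer_config(
    learning_rate = 1e300, batch_size = 5, local_epochs = 2),
    with_replacement = FALSE, eval_split = 0, seed = 2)
  expect_error(run_federated_training(coh, part, ms, cfg), "all clients failed")
})

test_that("subsampled federated estimates converge to the centralized fit", {
  # per-patient federation with 10% participation reaches the pooled MLE
  sup <- vapply(1:10, function(s) {
    coh <- generate_tabular_cohort(small_spec(seed = 100 + s, n = 5000L))
    ms <- glm_spec(c("x1", "x2"))
    fed <- run_federated_training(
      coh, partition_per_patient(coh), ms,
      fed_config(rounds = 300, participation = 0.1,
                 optimizer = optimizer_config(learning_rate = 0.3),
                 eval_split = 0, seed = s))
    ml <- run_centralized_training(coh, ms, method = "irls")
    max(abs(fed$params$values - ml$params$values))
  }, numeric(1))
  expect_true(all(sup < 0.05))
})

test_that("validation AUC does not degrade as participation grows", {
  aucs <- vapply(c(0.05, 0.2, 1), function(f) {
    mean(vapply(1:3, function(s) {
      coh <- generate_tabular_cohort(small_spec(seed = 200 + s, n = 2000L))
      run <- run_federated_training(
        coh, partition_per_patient(coh), glm_spec(c("x1", "x2")),
        fed_config(rounds = 150, participation = f,
                   optimizer = optimizer_config(learning_rate = 0.8),
                   eval_split = 0.2, eval_every = 150, seed = s))
      va <- run$trace$val_auc
      va[max(which(!is.na(va)))]
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(aucs ~ log(c(0.05, 0.2, 1)))
  expect_gt(coef(fit)[2], -0.005)  # non-decreasing up to seed noise
})

test_that("the centralized IRLS anchor handles the small-cohort regime quickly", {
  coh <- generate_tabular_cohort(hf_spec(seed = 12))
  ms <- glm_spec(fedstudy:::design_names(coh$spec))
  t0 <- Sys.time()
  fit <- run_centralized_training(coh, ms, method = "irls")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_true(fit$converged)
  ref <- stats::glm.fit(cbind(1, fedstudy:::cohort_design(coh)),
                        coh$data$outcome, family = stats::binomial())
  expect_equal(unname(fit$params$values), unname(ref$coefficients),
               tolerance = 1e-10)
})
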