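make_glm_batch <- function(seed = 1, n = 20, p = 5) {
  with(list(), {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    model_batch(x, rbinom(n, 1, 0.4))
  })
}

test_that("the loss matches its literal formula", {
  # all-zero logistic parameters on a balanced batch: mean NLL = log 2
  spec <- glm_spec(c("x1", "x2"))
  p0 <- init_params(spec)
  b <- model_batch(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
  expect_equal(as.numeric(local_loss(p0, b, spec)), log(2), tolerance = 1e-12)

  # stated penalty arithmetic: w = 0.3, l2 = 0.01 adds 0.01 * 0.09
  sp1 <- glm_spec("x", l2 = 0.01, intercept = FALSE)
  pw <- fedstudy:::new_params(0.3, fedstudy:::shape_registry(sp1))
  b1 <- model_batch(matrix(0, 4, 1), c(0, 1, 0, 1))
  expect_equal(as.numeric(local_loss(pw, b1, sp1)) - log(2), 0.01 * 0.09,
               tolerance = 1e-12)

  # random GLM against an independently coded per-example summation
  for (link in c("logit", "log")) {
    spec <- glm_spec(paste0("x", 1:5), link = link, l1 = 0.003, l2 = 0.02)
    b <- make_glm_batch(7)
    if (link == "log") b$x <- -abs(b$x)  # keep linear predictor negative
    set.seed(8)
    th <- c(-0.5, rnorm(5, 0, 0.3))
    pp <- fedstudy:::new_params(th, fedstudy:::shape_registry(spec))
    eta <- th[1] + drop(b$x %*% th[-1])
    mu <- if (link == "logit") 1 / (1 + exp(-eta)) else exp(pmin(eta, 0))
    nll <- -mean(b$y * log(mu) + (1 - b$y) * log(1 - pmin(mu, 1 - 1e-12)))
    oracle <- nll + 0.003 * sum(abs(th[-1])) + 0.02 * sum(th[-1]^2)
    expect_equal(as.numeric(local_loss(pp, b, spec)), oracle, tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with central finite differences", {
  # logit GLM
  spec <- glm_spec(paste0("x", 1:5), l1 = 0.001, l2 = 0.01)
  b <- make_glm_batch(3)
  set.seed(4)
  pp <- fedstudy:::new_params(rnorm(6, 0, 0.4), fedstudy:::shape_registry(spec))
  g <- local_grad(pp, b, spec)
  fd <- grad_fd(pp, b, spec)
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)

  # log-link GLM (away from the clamp)
  specl <- glm_spec(paste0("x", 1:3), link = "log", l2 = 0.01)
  set.seed(5)
  xl <- -abs(matrix(rnorm(45), 15, 3))
  bl <- model_batch(xl, rbinom(15, 1, 0.3))
  pl <- fedstudy:::new_params(c(-1, 0.2, 0.1, -0.3),
                              fedstudy:::shape_registry(specl))
  gl <- local_grad(pl, bl, specl)
  fdl <- grad_fd(pl, bl, specl)
  expect_lt(max(abs(gl - fdl)) / max(abs(fdl)), 1e-6)

  # embedding MLP, both poolings and activations
  for (pool in c("sum", "mean")) {
    for (act in c("relu", "tanh")) {
      spec <- mlp_spec(7, embedding_dim = 3, pooling = pool,
                       hidden_sizes = c(4, 3), activation = act,
                       l1 = 0.001, l2 = 0.01)
      pm <- init_params(spec, seed = 4)
      set.seed(6)
      X <- matrix(rpois(6 * 7, 2), 6, 7)
      bm <- model_batch(X, c(1, 0, 1, 0, 1, 0))
      gm <- local_grad(pm, bm, spec)
      fdm <- grad_fd(pm, bm, spec)
      expect_lt(max(abs(gm - fdm)) / max(abs(fdm)), 1e-4)
    }
  }

  # tabular MLP (no embedding block)
  spec0 <- mlp_spec(0, input_dim = 4, hidden_sizes = 3, l2 = 0.01)
  p0 <- init_params(spec0, seed = 2)
  set.seed(7)
  b0 <- model_batch(matrix(rnorm(32), 8, 4), rbinom(8, 1, 0.5))
  g0 <- local_grad(p0, b0, spec0)
  fd0 <- grad_fd(p0, b0, spec0)
  expect_lt(max(abs(g0 - fd0)) / max(abs(fd0)), 1e-5)
})

test_that("loss is invariant to row order in a full batch", {
  spec <- glm_spec(paste0("x", 1:5), l1 = 0.01)
  b <- make_glm_batch(11)
  set.seed(12)
  pp <- fedstudy:::new_params(rnorm(6, 0, 0.3), fedstudy:::shape_registry(spec))
  ord <- sample(length(b$y))
  b2 <- list(x = b$x[ord, ], y = b$y[ord])
  expect_equal(as.numeric(local_loss(pp, b, spec)),
               as.numeric(local_loss(pp, b2, spec)), tolerance = 1e-14)
})

test_that("local updates take the documented optimizer steps", {
  spec <- glm_spec(paste0("x", 1:5))
  b <- make_glm_batch(21)
  set.seed(22)
  pp <- fedstudy:::new_params(rnorm(6, 0, 0.2), fedstudy:::shape_registry(spec))

  # zero learning rate is a no-op
  up0 <- local_update(pp, b, spec, optimizer_config(learning_rate = 0))
  expect_identical(up0$values, pp$values)

  # one full-batch sgd step equals params - lr * grad (finite differences)
  up <- local_update(pp, b, spec, optimizer_config(learning_rate = 0.3))
  fd <- grad_fd(pp, b, spec, h = 1e-6)
  expect_lt(max(abs(up$values - (pp$values - 0.3 * fd))) /
              max(abs(0.3 * fd)), 1e-5)

  # minibatch order is seeded: same seed, same result
  opt <- optimizer_config(learning_rate = 0.1, batch_size = 5, local_epochs = 2)
  expect_identical(local_update(pp, b, spec, opt, seed = 9)$values,
                   local_update(pp, b, spec, opt, seed = 9)$values)

  # adam runs and returns finite parameters on an EHR cohort at the
  # cross-device setting (lr 0.01)
  ehr <- generate_ehr_cohort(tiny_ehr_spec(seed = 2))
  mspec <- tiny_mlp()
  pm <- init_params(mspec, seed = 1)
  bm <- model_batch(token_matrix(ehr), ehr$data$outcome)
  upm <- local_update(pm, bm, mspec,
                      optimizer_config("adam", learning_rate = 0.01,
                                       batch_size = 16, local_epochs = 1))
  expect_true(all(is.finite(upm$values)))
  expect_false(identical(upm$values, pm$values))
})

test_that("predicted probabilities invert the link exactly", {
  spec <- glm_spec(c("x1", "x2"))
  p0 <- init_params(spec)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(predict_proba(p0, X, spec), rep(0.5, 10))

  slog <- glm_spec(c("x1", "x2"), link = "log")
  expect_equal(predict_proba(init_params(slog), X, slog), rep(1, 10))

  set.seed(31)
  th <- c(-0.4, 0.6, -0.3)
  pp <- fedstudy:::new_params(th, fedstudy:::shape_registry(spec))
  expect_equal(predict_proba(pp, X, spec),
               1 / (1 + exp(-(th[1] + drop(X %*% th[-1])))), tolerance = 1e-12)
  pl <- fedstudy:::new_params(th, fedstudy:::shape_registry(slog))
  expect_equal(predict_proba(pl, X, slog),
               pmin(exp(pmin(th[1] + drop(X %*% th[-1]), 0)), 1),
               tolerance = 1e-12)

  expect_error(predict_proba(pp, matrix(0, 2, 5), spec), "columns")
})

test_that("parameter counting matches the shape registry and flat length", {
  expect_equal(count_params(glm_spec(paste0("x", 1:12))), 13L)
  expect_equal(count_params(mlp_spec(10, embedding_dim = 4, hidden_sizes = 3)),
               10 * 4 + (4 * 3 + 3) + (3 * 1 + 1))
  for (s in 1:5) {
    set.seed(s)
    spec <- mlp_spec(sample(5:50, 1), embedding_dim = sample(2:8, 1),
                     hidden_sizes = sample(2:16, sample(1:3, 1)))
    expect_equal(count_params(spec), length(init_params(spec, s)$values))
  }
})

test_that("parameters round-trip through the JSON checkpoint format", {
  spec <- mlp_spec(9, embedding_dim = 3, hidden_sizes = c(4, 2), l1 = 1e-4)
  pm <- init_params(spec, seed = 12)
  tmp <- file.path(tempdir(), "params.json")
  write_params(pm, tmp)
  back <- read_params(tmp)
  expect_equal(back$values, pm$values, tolerance = 1e-15)
  expect_equal(back$registry, pm$registry)
  expect_equal(param_block(back, "W2"), param_block(pm, "W2"))
})

test_that("unpenalized gradient descent reaches the maximum-likelihood fit", {
  coh <- generate_tabular_cohort(small_spec(seed = 14, n = 500L))
  spec <- glm_spec(c("x1", "x2"))
  gd <- run_centralized_training(coh, spec,
                                 optimizer_config(learning_rate = 1.5),
                                 max_iter = 4000, tol = 1e-9)
  ml <- stats::glm(outcome ~ x1 + x2, stats::binomial(), coh$data)
  expect_lt(max(abs(gd$params$values - coef(ml))), 1e-4)

  # degenerate design is reported
  coh$data$x2 <- 1
  expect_warning(
    run_centralized_training(coh, spec, optimizer_config(), max_iter = 2),
    "non-identifiable")
})
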