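#' Penalized loss, gradient, and predictions
#'
#' The training objective shared by the centralized and federated paths is
#' the mean per-example Bernoulli negative log-likelihood plus
#' `l1 * sum(|w|) + l2 * sum(w^2)` over penalized blocks (intercepts and
#' biases excluded). For the log link the linear predictor is clamped at 0
#' (probability 1) inside the likelihood, and the number of clamped rows is
#' reported via the `"clamped"` attribute so training traces can flag it.
#'
#' @param params A `model_params`.
#' @param batch A list `list(x =, y =)`: design (or token-count) matrix
#'   and 0/1 outcomes. See [model_batch()].
#' @param spec The matching `model_spec`.
#' @return `local_loss()`: a finite scalar with attribute `"clamped"`.
#'   `local_grad()`: the flat gradient vector.
#' @export
local_loss <- function(params, batch, spec) {
  stopifnot(nrow(batch$x) >= 1L, all(batch$y %in% c(0, 1)))
  fw <- model_forward(params, batch$x, spec)
  nll <- mean(bernoulli_nll(fw$eta, batch$y, spec))
  w <- params$values[penalty_mask(params$registry)]
  val <- nll + spec$l1 * sum(abs(w)) + spec$l2 * sum(w^2)
  attr(val, "clamped") <- fw$clamped
  val
}

#' @rdname local_loss
#' @export
local_grad <- function(params, batch, spec) {
  fw <- model_forward(params, batch$x, spec, keep_cache = TRUE)
  n <- length(batch$y)
  # d(mean NLL)/d(eta) per row
  if (glm_link(spec) == "logit") {
    deta <- (fw$prob - batch$y) / n
  } else {
    p <- pmin(fw$prob, 1 - 1e-12)
    deta <- (-batch$y + (1 - batch$y) * p / (1 - p)) / n
    deta[fw$eta_raw > 0] <- 0  # clamped region: flat
  }
  g <- model_backward(params, batch$x, deta, spec, fw$cache)
  mask <- penalty_mask(params$registry)
  w <- params$values
  g[mask] <- g[mask] + spec$l1 * sign(w[mask]) + 2 * spec$l2 * w[mask]
  g
}

glm_link <- function(spec) if (spec$kind == "glm") spec$link else "logit"

# Stable Bernoulli NLL given the (clamped) linear predictor.
bernoulli_nll <- function(eta, y, spec) {
  if (glm_link(spec) == "log") {
    p <- pmin(exp(eta), 1 - 1e-12)
    -(y * log(p) + (1 - y) * log1p(-p))
  } else {
    pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta
  }
}

# Forward pass: returns prob, eta (clamped for log link), eta_raw,
# clamped count, and (optionally) the layer cache for backprop.
model_forward <- function(params, x, spec, keep_cache = FALSE) {
  if (spec$kind == "glm") {
    if (ncol(x) != length(spec$feature_names)) {
      stopf("design has %d columns but spec expects %d",
            ncol(x), length(spec$feature_names))
    }
    beta <- param_block(params, "coef")
    eta <- drop(x %*% beta)
    if (spec$intercept) eta <- eta + param_block(params, "(Intercept)")
    eta_raw <- eta
    clamped <- 0L
    if (spec$link == "log") {
      clamped <- sum(eta > 0)
      eta <- pmin(eta, 0)
      prob <- exp(eta)
    } else {
      prob <- sigmoid(eta)
    }
    return(list(prob = prob, eta = eta, eta_raw = eta_raw,
                clamped = clamped, cache = NULL))
  }
  # MLP
  act <- switch(spec$activation, relu = function(a) pmax(a, 0), tanh = tanh)
  if (spec$vocab_size > 0L) {
    if (ncol(x) != spec$vocab_size) {
      stopf("token matrix has %d columns but vocab_size is %d",
            ncol(x), spec$vocab_size)
    }
    E <- param_block(params, "embedding")
    E <- matrix(E, spec$vocab_size, spec$embedding_dim)
    xin <- x
    if (spec$pooling == "mean") {
      s <- rowSums(x)
      xin <- x / ifelse(s > 0, s, 1)
    }
    H <- xin %*% E
  } else {
    if (ncol(x) != spec$input_dim) {
      stopf("input has %d columns but spec expects %d", ncol(x), spec$input_dim)
    }
    xin <- x
    H <- x
  }
  L <- length(spec$hidden_sizes)
  cache <- list(xin = xin, H = vector("list", L + 1L),
                A = vector("list", L + 1L))
  cache$H[[1L]] <- H
  for (i in seq_len(L)) {
    W <- as_mat(param_block(params, paste0("W", i)))
    b <- param_block(params, paste0("b", i))
    A <- sweep(cache$H[[i]] %*% W, 2L, -b)
    cache$A[[i]] <- A
    cache$H[[i + 1L]] <- act(A)
  }
  Wout <- as_mat(param_block(params, paste0("W", L + 1L)))
  bout <- param_block(params, paste0("b", L + 1L))
  eta <- drop(cache$H[[L + 1L]] %*% Wout) + bout
  list(prob = sigmoid(eta), eta = eta, eta_raw = eta, clamped = 0L,
       cache = if (keep_cache) cache)
}

as_mat <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 1L)

# Backward pass: gradient of the (unpenalized) mean NLL in flat layout.
model_backward <- function(params, x, deta, spec, cache) {
  registry <- params$registry
  if (spec$kind == "glm") {
    g <- list()
    if (spec$intercept) g[["(Intercept)"]] <- sum(deta)
    g[["coef"]] <- drop(crossprod(x, deta))
    return(flatten_blocks(g, registry))
  }
  L <- length(spec$hidden_sizes)
  actp <- switch(spec$activation,
    relu = function(a) (a > 0) * 1,
    tanh = function(a) 1 - tanh(a)^2)
  g <- list()
  dA <- matrix(deta, ncol = 1L)
  for (i in (L + 1L):1L) {
    Hprev <- cache$H[[i]]
    g[[paste0("W", i)]] <- crossprod(Hprev, dA)
    g[[paste0("b", i)]] <- colSums(dA)
    if (i > 1L) {
      W <- as_mat(param_block(params, paste0("W", i)))
      dH <- dA %*% t(W)
      dA <- dH * actp(cache$A[[i - 1L]])
    } else {
      dH0 <- dA %*% t(as_mat(param_block(params, "W1")))
      if (spec$vocab_size > 0L) {
        # note dA at this point is already the first hidden pre-activation
        # gradient; recover input gradient through W1
        g[["embedding"]] <- crossprod(cache$xin, dH0)
      }
    }
  }
  flatten_blocks(g, registry)
}

flatten_blocks <- function(g, registry) {
  unlist(lapply(registry, function(b) {
    v <- g[[b$name]]
    if (is.null(v)) numeric(b$nrow * b$ncol) else as.numeric(v)
  }), use.names = FALSE)
}

#' Bundle a design matrix and outcomes for the loss functions
#'
#' @param x Numeric matrix (design or token counts).
#' @param y 0/1 outcome vector of length `nrow(x)`.
#' @return A list `list(x =, y =)`.
#' @export
model_batch <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  list(x = x, y = as.numeric(y))
}

#' Predicted outcome probabilities
#'
#' Logit link: `sigmoid(x %*% beta)`. Log link: `min(exp(x %*% beta), 1)`
#' (a positive linear predictor is truncated at probability 1, the
#' documented safeguard). MLP: full forward pass ending in a sigmoid.
#'
#' @inheritParams local_loss
#' @param x Matrix of rows to score.
#' @return Probabilities in `[0, 1]`.
#' @export
predict_proba <- function(params, x, spec) {
  model_forward(params, as.matrix(x), spec)$prob
}
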