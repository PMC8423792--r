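#' Local optimizer configuration
#'
#' Settings for the client-side optimization step of federated averaging
#' (and for the pooled gradient-descent baseline). Defaults follow the
#' convention that GLM clients take one full-batch step per round, which
#' makes full-participation federated averaging coincide with centralized
#' gradient descent.
#'
#' @param algorithm `"sgd"` or `"adam"`.
#' @param learning_rate Step size (> 0, or 0 for a no-op step).
#' @param local_epochs Passes over the client's data per round (>= 1).
#' @param batch_size Minibatch size; `Inf` means full batch.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("sgd", "adam"),
                             learning_rate = 0.1,
                             local_epochs = 1L,
                             batch_size = Inf,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.numeric(learning_rate), learning_rate >= 0,
            is_count(local_epochs),
            (is.infinite(batch_size) || is_count(batch_size)))
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 local_epochs = as.integer(local_epochs),
                 batch_size = batch_size,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "optimizer_config")
}

#' One client's local training pass
#'
#' Runs `local_epochs` passes of seeded minibatch gradient steps on the
#' penalized loss, starting from the current global parameters, and
#' returns the updated parameter vector. With `batch_size = Inf` and one
#' epoch this is a single full-batch step `params - lr * grad`.
#'
#' @inheritParams local_loss
#' @param opt An [optimizer_config()].
#' @param seed Seed for the minibatch shuffle (batch order is the only
#'   randomness).
#' @return Updated `model_params`.
#' @export
local_update <- function(params, batch, spec, opt = optimizer_config(),
                         seed = 1L) {
  stopifnot(inherits(opt, "optimizer_config"), length(batch$y) >= 1L)
  n <- length(batch$y)
  bs <- if (is.infinite(opt$batch_size)) n else min(opt$batch_size, n)
  full <- bs >= n
  w <- params$values
  m1 <- m2 <- numeric(length(w))
  step <- 0L
  for (ep in seq_len(opt$local_epochs)) {
    ord <- if (full) seq_len(n) else {
      with_seed(derive_seed(seed, ep), sample.int(n))
    }
    starts <- seq(1L, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      g <- local_grad(new_params(w, params$registry),
                      list(x = batch$x[idx, , drop = FALSE], y = batch$y[idx]),
                      spec)
      if (any(!is.finite(g))) {
        stopf("non-finite gradient in local update (step %d)", step + 1L)
      }
      step <- step + 1L
      if (opt$algorithm == "sgd") {
        w <- w - opt$learning_rate * g
      } else {
        m1 <- opt$beta1 * m1 + (1 - opt$beta1) * g
        m2 <- opt$beta2 * m2 + (1 - opt$beta2) * g^2
        mh <- m1 / (1 - opt$beta1^step)
        vh <- m2 / (1 - opt$beta2^step)
        w <- w - opt$learning_rate * mh / (sqrt(vh) + opt$eps)
      }
    }
  }
  new_params(w, params$registry)
}
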