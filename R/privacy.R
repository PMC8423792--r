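#' Differential-privacy configuration for federated training
#'
#' Central DP clips each client update to L2 norm `clip_norm` and adds
#' Gaussian noise at the aggregator; local DP clips and noises on each
#' client before upload. `noise_multiplier` expresses the noise standard
#' deviation in units of the clipping norm at the point of application:
#' central noise has per-coordinate sd `z * S / m` after averaging `m`
#' updates, local noise has sd `z * S` on each update.
#'
#' @param mode `"none"`, `"central"`, or `"local"`.
#' @param clip_norm Clipping norm S (> 0).
#' @param noise_multiplier Noise multiplier z (>= 0).
#' @param delta Privacy slack delta in (0, 1); a warning is emitted if
#'   `delta >= 1/n` when the cohort size is known to the engine.
#' @param seed Seed for the noise stream.
#' @return An object of class `dp_config`.
#' @export
dp_config <- function(mode = c("none", "central", "local"),
                      clip_norm = 1, noise_multiplier = 0,
                      delta = 1e-5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "none") {
    stopifnot(clip_norm > 0, noise_multiplier >= 0, delta > 0, delta < 1)
  }
  structure(list(mode = mode, clip_norm = clip_norm,
                 noise_multiplier = noise_multiplier,
                 delta = delta, seed = as.integer(seed)),
            class = "dp_config")
}

#' Clip an update vector to an L2 norm bound
#'
#' Returns `delta * min(1, S / ||delta||_2)`: direction preserved, norm at
#' most `S`. Idempotent.
#'
#' @param delta Numeric update vector.
#' @param S Clipping norm (> 0).
#' @return The clipped vector.
#' @export
clip_update <- function(delta, S) {
  stopifnot(S > 0)
  nrm <- sqrt(sum(delta^2))
  if (nrm <= S || nrm == 0) delta else delta * (S / nrm)
}

#' Central-DP aggregation of client updates
#'
#' Clips each update to `S`, takes the *unweighted* mean over the `m`
#' contributors (the uniform mean is what gives the Gaussian mechanism its
#' `S / m` sensitivity; this is the one place federated aggregation
#' deviates from size-weighted averaging), and adds per-coordinate
#' Gaussian noise with sd `z * S / m`.
#'
#' @param deltas List of equal-length update vectors (length `m >= 1`).
#' @param S Clipping norm.
#' @param z Noise multiplier.
#' @return The noisy mean update vector.
#' @export
central_dp_aggregate <- function(deltas, S, z) {
  m <- length(deltas)
  stopifnot(m >= 1L)
  clipped <- lapply(deltas, clip_update, S = S)
  avg <- Reduce(`+`, clipped) / m
  if (z > 0) avg <- avg + stats::rnorm(length(avg), 0, z * S / m)
  avg
}

#' Local-DP perturbation of one client update
#'
#' Applied on-client before upload: clip to `S`, then add Gaussian noise
#' with per-coordinate sd `z * S`.
#'
#' @inheritParams central_dp_aggregate
#' @param delta One update vector.
#' @return The noisy clipped vector.
#' @export
local_dp_perturb <- function(delta, S, z) {
  out <- clip_update(delta, S)
  if (z > 0) out <- out + stats::rnorm(length(out), 0, z * S)
  out
}

#' Classical Gaussian-mechanism calibration
#'
#' The analytic bound `epsilon = sqrt(2 * log(1.25 / delta)) / z` for one
#' release of a Gaussian mechanism with noise multiplier `z`, and its
#' exact inverse `calibrate_noise()`. Used to report the per-round local
#' DP budget.
#'
#' @param z Noise multiplier (> 0).
#' @param epsilon Privacy budget (> 0).
#' @param delta Slack in (0, 1).
#' @return `gaussian_epsilon()`: epsilon; `calibrate_noise()`: z.
#' @examples
#' z <- calibrate_noise(1.36, 1e-9)
#' gaussian_epsilon(z, 1e-9)  # 1.36
#' @export
gaussian_epsilon <- function(z, delta) {
  if (!is.numeric(z) || any(z <= 0)) stopf("z must be > 0")
  if (!is.numeric(delta) || any(delta <= 0) || any(delta >= 1)) {
    stopf("delta must lie in (0, 1)")
  }
  sqrt(2 * log(1.25 / delta)) / z
}

#' @rdname gaussian_epsilon
#' @export
calibrate_noise <- function(epsilon, delta) {
  if (!is.numeric(epsilon) || any(epsilon <= 0)) stopf("epsilon must be > 0")
  if (!is.numeric(delta) || any(delta <= 0) || any(delta >= 1)) {
    stopf("delta must lie in (0, 1)")
  }
  sqrt(2 * log(1.25 / delta)) / epsilon
}

# RDP of the Poisson-subsampled Gaussian mechanism at integer order alpha
# (binomial-expansion bound); reduces exactly to alpha / (2 z^2) at q = 1.
rdp_subsampled_gaussian <- function(alpha, z, q) {
  if (q >= 1) return(alpha / (2 * z^2))
  k <- 0:alpha
  logterms <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
    k * (k - 1) / (2 * z^2)
  m <- max(logterms)
  (m + log(sum(exp(logterms - m)))) / (alpha - 1)
}

#' Multi-round privacy accounting for central DP
#'
#' Composes `T` rounds of the subsampled Gaussian mechanism (client
#' sampling fraction `q`, noise multiplier `z`) via Renyi differential
#' privacy: for each order `alpha` on an integer grid 2..64 joined with a
#' log-spaced grid up to 512, the total RDP is `T * RDP(alpha)` and the
#' reported epsilon is the minimum over orders of
#' `T * RDP(alpha) + log(1/delta) / (alpha - 1)`.
#'
#' @param z Noise multiplier (> 0).
#' @param q Per-round client sampling fraction in (0, 1].
#' @param T_rounds Number of rounds (>= 1).
#' @param delta Target delta in (0, 1).
#' @return Cumulative epsilon (possibly `Inf` when `z` is too small for
#'   any finite bound on the grid).
#' @export
compose_accountant <- function(z, q, T_rounds, delta) {
  stopifnot(z > 0, q > 0, q <= 1, T_rounds >= 1, delta > 0, delta < 1)
  orders <- unique(c(2:64, round(exp(seq(log(64), log(512), length.out = 20)))))
  eps <- vapply(orders, function(a) {
    r <- rdp_subsampled_gaussian(a, z, q)
    if (!is.finite(r)) return(Inf)
    T_rounds * r + log(1 / delta) / (a - 1)
  }, numeric(1))
  min(eps)
}

# Cumulative privacy spend bookkeeping written into training traces.
privacy_spend <- function(dp, q, round, n = NULL) {
  if (is.null(dp) || dp$mode == "none") {
    return(list(mode = "none", eps_round = NA_real_, eps_cum = NA_real_,
                delta = NA_real_))
  }
  if (dp$mode == "local") {
    eps_round <- if (dp$noise_multiplier > 0) {
      gaussian_epsilon(dp$noise_multiplier, dp$delta)
    } else Inf
    # basic composition of the per-round budget; reported with the caveat
    # that the headline local guarantee is per round
    list(mode = "local", eps_round = eps_round,
         eps_cum = round * eps_round, delta = dp$delta)
  } else {
    eps_cum <- if (dp$noise_multiplier > 0) {
      compose_accountant(dp$noise_multiplier, q, round, dp$delta)
    } else Inf
    list(mode = "central", eps_round = NA_real_, eps_cum = eps_cum,
         delta = dp$delta)
  }
}
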