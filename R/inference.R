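#' Fisher information from pooled or per-client data
#'
#' Expected information of the binomial GLM at `params`:
#' `sum_i w_i x_i x_i'` with the IRLS weight `w = mu (1 - mu)` for the
#' logit link and `w = mu / (1 - mu)` for the log link. Because the sum is
#' additive over rows, per-client partial sums over any partition equal
#' the pooled computation exactly, so the federated and centralized
#' inference paths produce the identical matrix.
#'
#' @param params A `model_params` (converged GLM fit).
#' @param x Design matrix without intercept column, or a list of such
#'   matrices (one per client) whose contributions are summed.
#' @param spec A `glm_spec`.
#' @return The `(p+1) x (p+1)` information matrix (intercept first when
#'   the spec has one).
#' @export
fisher_information <- function(params, x, spec) {
  stopifnot(inherits(spec, "glm_spec"))
  if (is.list(x) && !is.data.frame(x)) {
    return(Reduce(`+`, lapply(x, fisher_information, params = params, spec = spec)))
  }
  x <- as.matrix(x)
  X <- if (spec$intercept) cbind(`(Intercept)` = 1, x) else x
  mu <- model_forward(params, x, spec)$prob
  w <- if (spec$link == "logit") mu * (1 - mu) else mu / pmax(1 - mu, 1e-12)
  crossprod(X * sqrt(w))
}

# Inverse information with a pseudo-inverse fallback for singular designs.
information_inverse <- function(info) {
  out <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular Fisher information: using pseudo-inverse (model may be non-identifiable)",
            call. = FALSE)
    s <- svd(info)
    pos <- s$d > max(s$d) * 1e-12
    out <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  dimnames(out) <- dimnames(info)
  out
}

#' Wald interval and test for one coefficient
#'
#' `estimate +/- z_level * se`, exponentiated to the odds-ratio /
#' risk-ratio scale on request, with the two-sided normal p-value.
#'
#' @param beta Coefficient estimate(s).
#' @param se Standard error(s) (> 0).
#' @param level Confidence level (default 0.95).
#' @param exponentiate Return `exp()` of the point estimate and bounds.
#' @return A data frame with columns `point`, `lower`, `upper`, `p`.
#' @export
wald_interval <- function(beta, se, level = 0.95, exponentiate = FALSE) {
  stopifnot(all(se > 0), level > 0, level < 1)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lo <- beta - zc * se
  hi <- beta + zc * se
  p <- 2 * stats::pnorm(-abs(beta / se))
  if (exponentiate) {
    data.frame(point = exp(beta), lower = exp(lo), upper = exp(hi), p = p)
  } else {
    data.frame(point = beta, lower = lo, upper = hi, p = p)
  }
}

#' Cluster-robust (sandwich) covariance from per-cluster score sums
#'
#' `I^{-1} (sum_g s_g s_g') I^{-1}` with `s_g` the score vector summed
#' within cluster `g` at the fitted coefficients. Cluster score sums are
#' additive over silos, so the matrix is computable federatedly by
#' summing per-silo contributions. With every row its own cluster this is
#' the heteroskedasticity-robust (HC0) sandwich.
#'
#' @inheritParams fisher_information
#' @param y 0/1 outcomes.
#' @param cluster Cluster id per row (>= 2 distinct values).
#' @return The robust covariance matrix of the coefficients.
#' @export
cluster_robust_cov <- function(params, x, y, cluster, spec) {
  stopifnot(inherits(spec, "glm_spec"))
  x <- as.matrix(x)
  cluster <- as.character(cluster)
  if (length(unique(cluster)) < 2L) stopf("need >= 2 clusters")
  X <- if (spec$intercept) cbind(`(Intercept)` = 1, x) else x
  fw <- model_forward(params, x, spec)
  mu <- fw$prob
  # score d(loglik_i)/d(eta): logit (y - mu); log (y - mu)/(1 - mu)
  u <- if (spec$link == "logit") y - mu else (y - mu) / pmax(1 - mu, 1e-12)
  S <- rowsum(X * u, cluster)
  meat <- crossprod(S)
  bread <- information_inverse(fisher_information(params, x, spec))
  out <- bread %*% meat %*% bread
  dimnames(out) <- dimnames(bread)
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties credited 1/2; computed from midranks.
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 outcomes (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined: one outcome class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified train/test evaluation
#'
#' The evaluation protocol of the replications: re-randomized stratified
#' splits, a model trained on each training portion, AUC measured on the
#' held-out portion, summarized as the mean with a percentile interval.
#' A split that loses an outcome class in either portion is redrawn and
#' counted.
#'
#' @param cohort A `fed_cohort`, `ehr_cohort`, or data frame with an
#'   `outcome` column.
#' @param trainer Function `(train, test) -> scores` returning one
#'   predicted score per held-out row; `train`/`test` are row-subset
#'   objects of the same type as `cohort`.
#' @param n_reps Number of repetitions (>= 2; the replicated protocol
#'   uses 100).
#' @param split Training fraction (default 0.8).
#' @param seed Root seed.
#' @param level Confidence level of the percentile interval.
#' @return List with `mean_auc`, `ci` (percentile bounds), `aucs`,
#'   and `n_redrawn`.
#' @export
repeated_split_evaluate <- function(cohort, trainer, n_reps = 100L,
                                    split = 0.8, seed = 1L, level = 0.95) {
  stopifnot(is_count(n_reps, min = 2), split > 0, split < 1)
  d <- cohort_rows(cohort)
  y <- d$outcome
  n <- length(y)
  subset_cohort <- function(idx) {
    if (inherits(cohort, "fed_cohort")) {
      structure(list(data = d[idx, , drop = FALSE], spec = cohort$spec),
                class = "fed_cohort")
    } else if (inherits(cohort, "ehr_cohort")) {
      structure(list(data = d[idx, , drop = FALSE],
                     tokens = cohort$tokens[idx], spec = cohort$spec),
                class = "ehr_cohort")
    } else {
      cohort[idx, , drop = FALSE]
    }
  }
  aucs <- numeric(n_reps)
  redrawn <- 0L
  for (r in seq_len(n_reps)) {
    repeat {
      sp <- stratified_split(y, 1 - split, derive_seed(seed, r * 1000L + redrawn))
      ok <- length(unique(y[sp$train])) == 2L && length(unique(y[sp$test])) == 2L
      if (ok) break
      redrawn <- redrawn + 1L
    }
    sc <- trainer(subset_cohort(sp$train), subset_cohort(sp$test))
    aucs[r] <- auc(sc, y[sp$test])
  }
  a <- (1 - level) / 2
  list(mean_auc = mean(aucs),
       ci = stats::quantile(aucs, c(a, 1 - a), names = FALSE),
       aucs = aucs, n_redrawn = redrawn)
}

#' Agreement report between centralized and federated fits
#'
#' Side-by-side comparison of a centralized fit with one or more
#' federated replications of the same model: per-feature coefficient
#' differences, indicators of confidence-interval overlap, and
#' same-conclusion flags at `alpha` (both fits significant with the same
#' direction of effect, or both non-significant).
#'
#' @param fit_central A `fedfit` (e.g. from [fedglm()] with
#'   `engine = "centralized"`).
#' @param fits_federated Named list of `fedfit` objects over the same
#'   features (e.g. per-patient and per-silo replications).
#' @param alpha Significance level for the conclusion flags.
#' @return An object of class `fed_agreement`: a long-format data frame
#'   `table` (one row per feature and regime) plus summary counts.
#' @export
agreement_report <- function(fit_central, fits_federated, alpha = 0.05) {
  stopifnot(inherits(fit_central, "fedfit"))
  if (inherits(fits_federated, "fedfit")) {
    fits_federated <- list(federated = fits_federated)
  }
  stopifnot(all(vapply(fits_federated, inherits, TRUE, "fedfit")))
  if (is.null(names(fits_federated))) {
    names(fits_federated) <- paste0("federated_", seq_along(fits_federated))
  }
  feats <- fit_central$table$feature
  rows <- lapply(names(fits_federated), function(nm) {
    f <- fits_federated[[nm]]
    if (!identical(f$table$feature, feats)) {
      stopf("feature mismatch between centralized fit and '%s'", nm)
    }
    ct <- fit_central$table
    ft <- f$table
    sig_c <- ct$p < alpha
    sig_f <- ft$p < alpha
    data.frame(
      regime = nm, feature = feats,
      estimate_central = ct$estimate, estimate_federated = ft$estimate,
      diff = ft$estimate - ct$estimate,
      ci_overlap = pmax(ct$ci_low, ft$ci_low) <= pmin(ct$ci_high, ft$ci_high),
      same_conclusion = (sig_c == sig_f) &
        (!sig_c | sign(ct$estimate) == sign(ft$estimate)),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 n_features = length(feats),
                 regimes = names(fits_federated),
                 alpha = alpha,
                 n_same_conclusion = tapply(tab$same_conclusion, tab$regime, sum),
                 n_ci_overlap = tapply(tab$ci_overlap, tab$regime, sum)),
            class = "fed_agreement")
}

#' @export
print.fed_agreement <- function(x, ...) {
  cat(sprintf("Agreement report: %d features, regimes: %s\n",
              x$n_features, paste(x$regimes, collapse = ", ")))
  for (r in x$regimes) {
    cat(sprintf("  %s: %d/%d same conclusion at alpha=%.2f, %d/%d CI overlap\n",
                r, x$n_same_conclusion[[r]], x$n_features, x$alpha,
                x$n_ci_overlap[[r]], x$n_features))
  }
  wide <- x$table
  cat("\n")
  print(utils::head(wide, 20L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a fit or agreement report
#'
#' Writes the coefficient table as flat CSV (one row per feature:
#' estimate, se, ratio, CI bounds, p) and the full result as JSON.
#'
#' @param x A `fedfit` or `fed_agreement`.
#' @param path File stem; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  tab <- x$table
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  keep <- x[setdiff(names(x), c("trace", "terms", "model"))]
  keep <- lapply(keep, function(v) {
    if (inherits(v, c("model_params"))) v$values else v
  })
  jsonlite::write_json(keep, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(path)
}
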