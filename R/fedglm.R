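#' Fit a binomial GLM by federated averaging (or centrally)
#'
#' The package's main modelling interface. Fits a logistic (odds-ratio
#' scale) or log-link binomial (risk-ratio scale) regression either by
#' federated averaging over a partition of the patients, or centrally on
#' the pooled data (IRLS when unpenalized, gradient descent otherwise).
#' Standard errors come from the unpenalized Fisher information evaluated
#' at the estimate -- computed from per-client additive sufficient
#' statistics, so the federated and centralized inference paths coincide
#' exactly -- or from the cluster-robust sandwich when `cluster` is given.
#'
#' @param formula Model formula; the response must be 0/1.
#' @param data A data frame, or a `fed_cohort` (its `data` is used).
#' @param link `"logit"` or `"log"`.
#' @param engine `"federated"` or `"centralized"`.
#' @param partition A `fed_partition`; defaults to per-patient federation
#'   (one client per row when the data has no `patient_id` column).
#' @param config A [fed_config()]; by default coefficients are fitted on
#'   all rows (`eval_split = 0`) since the endpoints here are
#'   coefficients, not holdout AUC.
#' @param dp Optional [dp_config()].
#' @param l1,l2 Penalty magnitudes (recorded in the report; intervals use
#'   the classical information regardless).
#' @param cluster Optional cluster id column name (or vector) for
#'   cluster-robust standard errors.
#' @param level Confidence level for the Wald intervals.
#' @return An object of class `c("fedglm", "fedfit")` with methods
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `predict`,
#'   `residuals`, `simulate`, and `plot`.
#' @examples
#' spec <- cohort_spec(400, list(covariate_spec("x", "binary")),
#'                     beta = c(-1, 0.7), seed = 3)
#' coh <- generate_tabular_cohort(spec)
#' fit <- fedglm(outcome ~ x, coh, config = fed_config(rounds = 150,
#'   optimizer = optimizer_config(learning_rate = 0.5), eval_split = 0))
#' summary(fit)
#' @export
fedglm <- function(formula, data, link = c("logit", "log"),
                   engine = c("federated", "centralized"),
                   partition = NULL,
                   config = fed_config(eval_split = 0),
                   dp = NULL, l1 = 0, l2 = 0,
                   cluster = NULL, level = 0.95) {
  link <- match.arg(link)
  engine <- match.arg(engine)
  df <- cohort_rows(data)
  mf <- stats::model.frame(formula, df)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stopf("response must be coded 0/1")
  X <- stats::model.matrix(mt, mf)
  has_int <- "(Intercept)" %in% colnames(X)
  Xf <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  spec <- glm_spec(colnames(Xf), link = link, l1 = l1, l2 = l2,
                   intercept = has_int)
  pid <- df$patient_id %||% seq_len(nrow(df))
  batch <- list(x = Xf, y = as.numeric(y), patient_id = pid)

  if (engine == "federated") {
    if (is.null(partition)) {
      partition <- partition_per_patient(data.frame(patient_id = pid))
    }
    run <- run_federated_training(batch, partition, spec, config, dp)
  } else {
    run <- if (l1 == 0 && l2 == 0) {
      run_centralized_training(batch, spec, method = "irls")
    } else {
      run_centralized_training(batch, spec, config$optimizer, method = "gd",
                               max_iter = max(config$rounds, 500L))
    }
  }
  beta <- run$params$values
  nm <- c(if (has_int) "(Intercept)", colnames(Xf))
  names(beta) <- nm

  # inference: unpenalized information at the estimate
  info_spec <- glm_spec(colnames(Xf), link = link, intercept = has_int)
  if (!is.null(cluster)) {
    cl <- if (is.character(cluster) && length(cluster) == 1L) df[[cluster]] else cluster
    V <- cluster_robust_cov(run$params, Xf, batch$y, cl, info_spec)
    se_type <- "cluster-robust"
  } else {
    V <- information_inverse(fisher_information(run$params, Xf, info_spec))
    se_type <- "model-based"
  }
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- nm
  ok <- se > 0
  ratio_name <- if (link == "logit") "or" else "rr"
  # CI bounds reported on the ratio (exp) scale, matching the endpoint
  wl <- wald_interval(beta[ok], se[ok], level = level, exponentiate = TRUE)
  tab <- data.frame(feature = nm, estimate = beta, se = se,
                    ratio = exp(beta),
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$ci_low[ok] <- wl$lower
  tab$ci_high[ok] <- wl$upper
  tab$p[ok] <- wl$p
  names(tab)[names(tab) == "ratio"] <- ratio_name

  last_auc <- if (inherits(run$trace$val_auc, "numeric")) {
    va <- run$trace$val_auc
    va <- va[!is.na(va)]
    if (length(va)) va[length(va)] else NA_real_
  } else NA_real_
  spend <- if (!is.null(dp) && dp$mode != "none") {
    run$trace$eps_cum[nrow(run$trace)]
  } else NA_real_

  structure(list(coefficients = beta, se = se, vcov = V, table = tab,
                 link = link, level = level, engine = engine,
                 se_type = se_type, l1 = l1, l2 = l2,
                 partition_unit = if (engine == "federated") partition$unit else "pooled",
                 auc = last_auc, dp_spend = spend,
                 trace = run$trace, params = run$params, spec = spec,
                 converged = run$converged %||% NA,
                 n = nrow(Xf), formula = formula, terms = mt,
                 xlevels = stats::.getXlevels(mt, mf),
                 seed = config$seed),
            class = c("fedglm", "fedfit"))
}

#' @export
print.fedglm <- function(x, digits = 4, ...) {
  cat(sprintf("Federated %s-link binomial GLM (%s engine, %s unit)\n",
              x$link, x$engine, x$partition_unit))
  cat(sprintf("  n = %d; penalties l1 = %g, l2 = %g; SEs: %s\n",
              x$n, x$l1, x$l2, x$se_type))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.fedglm <- function(object, ...) {
  structure(list(fit = object), class = "summary.fedglm")
}

#' @export
print.summary.fedglm <- function(x, digits = 4, ...) {
  f <- x$fit
  ratio <- if (f$link == "logit") "OR" else "RR"
  print(f)
  tab <- f$table
  names(tab) <- c("feature", "estimate", "se", ratio,
                  sprintf("%.0f%% low", 100 * f$level),
                  sprintf("%.0f%% high", 100 * f$level), "p")
  cat(sprintf("\n%s with %.0f%% Wald confidence intervals:\n",
              ratio, 100 * f$level))
  print(tab, row.names = FALSE, digits = digits)
  if (!is.na(f$auc)) cat(sprintf("\nValidation AUC: %.3f\n", f$auc))
  if (!is.na(f$dp_spend)) {
    cat(sprintf("Differential privacy: cumulative epsilon %.3g\n", f$dp_spend))
  }
  invisible(x)
}

#' @export
coef.fedglm <- function(object, ...) object$coefficients

#' @export
vcov.fedglm <- function(object, ...) object$vcov

#' @export
confint.fedglm <- function(object, parm, level = 0.95, exponentiate = FALSE, ...) {
  nm <- names(object$coefficients)
  if (missing(parm)) parm <- nm
  wl <- wald_interval(object$coefficients[parm], object$se[parm],
                      level = level, exponentiate = exponentiate)
  out <- as.matrix(wl[, c("lower", "upper")])
  rownames(out) <- parm
  out
}

fedglm_design <- function(object, newdata) {
  mf <- stats::model.frame(stats::delete.response(object$terms), newdata,
                           xlev = object$xlevels)
  X <- stats::model.matrix(stats::delete.response(object$terms), mf)
  X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
}

#' @export
predict.fedglm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  Xf <- fedglm_design(object, cohort_rows(newdata))
  fw <- model_forward(object$params, Xf, object$spec)
  unname(if (type == "response") fw$prob else fw$eta_raw)
}

#' @export
residuals.fedglm <- function(object, newdata = NULL,
                             type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stopf("supply the data used for the fit via `newdata`")
  d <- cohort_rows(newdata)
  y <- stats::model.response(stats::model.frame(object$terms, d))
  mu <- predict(object, d)
  unname(switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) * sqrt(-2 * (y * log(pmax(mu, 1e-12)) +
                                           (1 - y) * log(pmax(1 - mu, 1e-12))))))
}

#' @export
simulate.fedglm <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (is.null(newdata)) stopf("supply covariate rows via `newdata`")
  mu <- predict(object, cohort_rows(newdata))
  draws <- with_seed(seed %||% 1L, {
    replicate(nsim, stats::rbinom(length(mu), 1L, mu), simplify = FALSE)
  })
  out <- as.data.frame(draws, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' @export
plot.fedglm <- function(x, ...) {
  tr <- x$trace
  has_auc <- any(!is.na(tr$val_auc))
  graphics::par(mfrow = c(1, if (has_auc) 2 else 1))
  graphics::plot(tr$round, tr$train_loss, type = "l", xlab = "round",
                 ylab = "training loss", main = "Penalized loss", ...)
  if (has_auc) {
    ok <- !is.na(tr$val_auc)
    graphics::plot(tr$round[ok], tr$val_auc[ok], type = "l", xlab = "round",
                   ylab = "validation AUC", main = "Holdout AUC", ...)
  }
  invisible(x)
}

#' Train the embedding feed-forward classifier federatedly
#'
#' Fits the bag-of-tokens embedding network (embedding table, pooled into
#' fully connected hidden layers, sigmoid output) on an EHR-like cohort by
#' federated averaging, following the cross-device EHR configuration:
#' Adam local steps with learning rate 0.01, L1 penalty 1e-4 and L2
#' penalty 0.01 by default.
#'
#' @param cohort An `ehr_cohort`.
#' @param spec An [mlp_spec()]; defaults to hidden layers scaled for
#'   desk-size experiments.
#' @param partition A `fed_partition`; default per-patient.
#' @param config A [fed_config()]; default 16 clients per round.
#' @param dp Optional [dp_config()].
#' @return An object of class `c("fedmlp", "fedfit")` with `print`,
#'   `predict`, and `plot` methods.
#' @export
fed_mlp <- function(cohort,
                    spec = mlp_spec(cohort$spec$vocab_size,
                                    embedding_dim = 16L,
                                    hidden_sizes = c(32L, 16L),
                                    l1 = 1e-4, l2 = 0.01),
                    partition = partition_per_patient(cohort),
                    config = fed_config(
                      rounds = 100L, clients_per_round = 16L,
                      optimizer = optimizer_config("adam", learning_rate = 0.01,
                                                   batch_size = 16L)),
                    dp = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(spec, "mlp_spec"))
  run <- run_federated_training(cohort, partition, spec, config, dp)
  va <- run$trace$val_auc
  va <- va[!is.na(va)]
  structure(list(params = run$params, spec = spec, trace = run$trace,
                 auc = if (length(va)) va[length(va)] else NA_real_,
                 n_params = count_params(spec),
                 dp_spend = run$trace$eps_cum[nrow(run$trace)],
                 split = run$split, config = config,
                 table = data.frame(feature = "auc",
                                    estimate = if (length(va)) va[length(va)] else NA_real_,
                                    se = NA_real_, or = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_,
                                    p = NA_real_)),
            class = c("fedmlp", "fedfit"))
}

#' @export
print.fedmlp <- function(x, ...) {
  cat(sprintf("Federated embedding MLP: %d parameters\n", x$n_params))
  if (!is.na(x$auc)) cat(sprintf("  validation AUC %.3f\n", x$auc))
  invisible(x)
}

#' @export
predict.fedmlp <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "ehr_cohort")) token_matrix(newdata) else as.matrix(newdata)
  predict_proba(object$params, x, object$spec)
}

#' @export
plot.fedmlp <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$round, tr$train_loss, type = "l", xlab = "round",
                 ylab = "training loss", main = "Penalized loss", ...)
  invisible(x)
}
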