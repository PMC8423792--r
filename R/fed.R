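#' Federated training configuration
#'
#' Controls the federated-averaging loop: number of server rounds, how
#' many clients participate per round (an absolute count or a fraction of
#' the client pool, sampled uniformly, by default with replacement -- a
#' client drawn twice contributes with multiplicity), the local optimizer,
#' the server step size, and the stratified holdout fraction used for
#' validation AUC.
#'
#' @param rounds Number of server rounds T (>= 1).
#' @param clients_per_round Absolute clients per round m; mutually
#'   exclusive with `participation`.
#' @param participation Per-round participation fraction q in (0, 1];
#'   `m = max(1, round(q * N))`. When neither is given every client
#'   participates every round.
#' @param with_replacement Sample the per-round cohort with replacement.
#' @param optimizer An [optimizer_config()] for the local client step.
#' @param server_lr Server step size applied to the aggregated update.
#' @param seed Root seed; all sampling, batch order, splits, and DP noise
#'   derive from it.
#' @param eval_split Stratified holdout fraction in `[0, 1)` used for
#'   validation AUC (0 trains on everything and skips evaluation).
#' @param eval_every Compute validation AUC every this many rounds.
#' @return An object of class `fed_config`.
#' @export
fed_config <- function(rounds = 100L,
                       clients_per_round = NULL,
                       participation = NULL,
                       with_replacement = TRUE,
                       optimizer = optimizer_config(),
                       server_lr = 1,
                       seed = 1L,
                       eval_split = 0.2,
                       eval_every = 1L) {
  stopifnot(is_count(rounds), is_flag(with_replacement),
            inherits(optimizer, "optimizer_config"),
            server_lr > 0, eval_split >= 0, eval_split < 1,
            is_count(eval_every))
  if (!is.null(clients_per_round) && !is.null(participation)) {
    stopf("give clients_per_round or participation, not both")
  }
  if (!is.null(clients_per_round)) stopifnot(is_count(clients_per_round))
  if (!is.null(participation)) {
    stopifnot(participation > 0, participation <= 1)
  }
  structure(list(rounds = as.integer(rounds),
                 clients_per_round = clients_per_round,
                 participation = participation,
                 with_replacement = with_replacement,
                 optimizer = optimizer, server_lr = server_lr,
                 seed = as.integer(seed), eval_split = eval_split,
                 eval_every = as.integer(eval_every)),
            class = "fed_config")
}

#' Sample the per-round client cohort
#'
#' Draws `m` clients uniformly from the partition's client list using the
#' current RNG stream -- with replacement by default, so a client can
#' appear several times and then contributes with multiplicity to the
#' weighted average.
#'
#' @param partition A `fed_partition` (or character vector of client ids).
#' @param clients_per_round Absolute number to draw.
#' @param fraction Fraction of the pool (used when `clients_per_round` is
#'   `NULL`); `m = max(1, round(fraction * N))`.
#' @param with_replacement Sample with replacement.
#' @return Character vector of client ids of length `m` (a multiset when
#'   sampling with replacement).
#' @export
sample_clients <- function(partition, clients_per_round = NULL,
                           fraction = NULL, with_replacement = TRUE) {
  ids <- if (inherits(partition, "fed_partition")) {
    names(partition$client_sizes)
  } else as.character(partition)
  N <- length(ids)
  if (N == 0L) stopf("empty client pool")
  m <- if (!is.null(clients_per_round)) {
    as.integer(clients_per_round)
  } else {
    max(1L, as.integer(round((fraction %||% 1) * N)))
  }
  if (!with_replacement) m <- min(m, N)
  if (!with_replacement && m == N) return(ids)
  sample(ids, m, replace = with_replacement)
}

#' Weighted federated averaging of client updates
#'
#' Exact weighted mean `sum(w_k * delta_k) / sum(w_k)` with weights the
#' client example counts (FedAvg aggregation).
#'
#' @param deltas List of equal-length numeric update vectors.
#' @param weights Positive weights, one per update.
#' @return The aggregated update vector.
#' @export
aggregate_updates <- function(deltas, weights) {
  stopifnot(length(deltas) >= 1L, length(weights) == length(deltas),
            all(weights > 0))
  len <- lengths(deltas)
  if (any(len != len[1L])) stopf("update vectors differ in length")
  D <- matrix(unlist(deltas, use.names = FALSE), nrow = len[1L])
  drop(D %*% (weights / sum(weights)))
}

# ---- engine internals -------------------------------------------------

# Resolve (x, y, patient_id) from a cohort-like object for a model spec.
model_inputs <- function(cohort, spec) {
  if (is.list(cohort) && !inherits(cohort, c("fed_cohort", "ehr_cohort")) &&
      !is.null(cohort$x)) {
    x <- as.matrix(cohort$x)
    return(list(x = x, y = as.numeric(cohort$y),
                patient_id = cohort$patient_id %||% seq_len(nrow(x))))
  }
  if (spec$kind == "glm") {
    stopifnot(inherits(cohort, "fed_cohort"))
    x <- cohort_design(cohort)
    if (!identical(colnames(x), spec$feature_names)) {
      if (!all(spec$feature_names %in% colnames(x))) {
        stopf("cohort design lacks feature(s): %s",
              paste(setdiff(spec$feature_names, colnames(x)), collapse = ", "))
      }
      x <- x[, spec$feature_names, drop = FALSE]
    }
  } else if (spec$vocab_size > 0L) {
    stopifnot(inherits(cohort, "ehr_cohort"))
    x <- token_matrix(cohort)
  } else {
    x <- if (inherits(cohort, "ehr_cohort")) {
      expand_design(cohort$data, cohort$spec$demographics)
    } else {
      cohort_design(cohort)
    }
  }
  list(x = x, y = as.numeric(cohort$data$outcome),
       patient_id = cohort$data$patient_id)
}

# Stratified train/holdout split of row indices, seeded.
stratified_split <- function(y, eval_split, seed) {
  n <- length(y)
  if (eval_split <= 0) return(list(train = seq_len(n), test = integer(0)))
  with_seed(seed, {
    test <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(eval_split * length(idx)))
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

# Data-aware default initialization: a log-link GLM started at beta = 0
# sits exactly on the probability-1 clamp, so its intercept starts at the
# log empirical prevalence instead; everything else uses init_params().
default_init <- function(spec, y_train, seed) {
  params <- init_params(spec, seed = seed)
  if (spec$kind == "glm" && spec$link == "log" && spec$intercept) {
    p0 <- min(max(mean(y_train), 1e-3), 1 - 1e-3)
    params$values[1L] <- log(p0)
  }
  params
}

# Penalty-gradient vector shared by all clients at the current params.
penalty_grad <- function(values, registry, spec) {
  g <- numeric(length(values))
  mask <- penalty_mask(registry)
  g[mask] <- spec$l1 * sign(values[mask]) + 2 * spec$l2 * values[mask]
  g
}

# Vectorized per-client single-step deltas for GLM clients (one full-batch
# sgd step each). Returns a K x P matrix, rows ordered like `clients`.
glm_client_deltas <- function(params, x, y, rows_by_client, clients, spec, lr) {
  fw <- model_forward(params, x, spec)
  if (spec$link == "logit") {
    r <- fw$prob - y
  } else {
    p <- pmin(fw$prob, 1 - 1e-12)
    r <- -y + (1 - y) * p / (1 - p)
    r[fw$eta_raw > 0] <- 0
  }
  grp <- rep(seq_along(clients),
             times = vapply(rows_by_client[clients], length, integer(1)))
  idx <- unlist(rows_by_client[clients], use.names = FALSE)
  nk <- vapply(rows_by_client[clients], length, numeric(1))
  Sx <- rowsum(x[idx, , drop = FALSE] * r[idx], grp, reorder = TRUE) / nk
  G <- if (spec$intercept) {
    cbind(rowsum(r[idx], grp, reorder = TRUE) / nk, Sx)
  } else Sx
  pen <- penalty_grad(params$values, params$registry, spec)
  -lr * sweep(G, 2L, -pen)
}

#' Federated-averaging training loop
#'
#' For each of `rounds` server rounds: sample the client cohort, run each
#' sampled client's local update from the current global parameters, form
#' client deltas (local minus global), apply the differential-privacy hook
#' if configured, aggregate (example-count-weighted mean, or the uniform
#' noisy mean under central DP), and take a server step. Fully seeded:
#' the same cohort, partition, and configs reproduce the trace
#' bit-for-bit. GLM clients taking a single full-batch sgd step are
#' computed on a vectorized path that is algebraically identical to the
#' per-client loop.
#'
#' @param cohort A `fed_cohort`, `ehr_cohort`, or `list(x =, y =)` batch.
#' @param partition A `fed_partition` over the cohort's patients.
#' @param spec A `model_spec`.
#' @param config A [fed_config()].
#' @param dp An optional [dp_config()]; `NULL` or mode `"none"` disables
#'   privacy (identical trajectories to a zero-noise, infinite-clip
#'   central configuration up to the uniform-vs-weighted mean).
#' @param init Optional starting `model_params`.
#' @param .force_generic Bypass the vectorized GLM path and run the
#'   per-client loop (used to verify the two paths coincide).
#' @return An object of class `fed_train`: final `params`, per-round
#'   `trace` (sampled clients, aggregate update norm, training loss,
#'   validation AUC, cumulative privacy spend), the split indices, and
#'   the resolved configs.
#' @export
run_federated_training <- function(cohort, partition, spec, config = fed_config(),
                                   dp = NULL, init = NULL,
                                   .force_generic = FALSE) {
  stopifnot(inherits(partition, "fed_partition"),
            inherits(spec, "model_spec"), inherits(config, "fed_config"))
  if (!is.null(dp)) stopifnot(inherits(dp, "dp_config"))
  use_dp <- !is.null(dp) && dp$mode != "none"
  inp <- model_inputs(cohort, spec)
  n <- length(inp$y)
  if (use_dp && dp$delta >= 1 / n) {
    warning(sprintf("dp delta = %g is not < 1/n = %g", dp$delta, 1 / n),
            call. = FALSE)
  }
  split <- stratified_split(inp$y, config$eval_split, derive_seed(config$seed, 777L))
  rows_all <- client_row_index(partition, inp$patient_id)
  # restrict clients to their training rows; drop clients left empty
  rows_by_client <- lapply(rows_all, intersect, y = split$train)
  rows_by_client <- rows_by_client[lengths(rows_by_client) > 0L]
  clients_pool <- names(rows_by_client)
  N <- length(clients_pool)
  if (N == 0L) stopf("no client holds any training row")
  m <- if (!is.null(config$clients_per_round)) {
    config$clients_per_round
  } else {
    max(1L, as.integer(round((config$participation %||% 1) * N)))
  }
  q <- m / N
  opt <- config$optimizer
  sizes <- vapply(rows_by_client, length, numeric(1))
  fast <- !.force_generic && spec$kind == "glm" && opt$algorithm == "sgd" &&
    opt$local_epochs == 1L && opt$batch_size >= max(sizes)
  params <- init %||% default_init(spec, inp$y[split$train],
                                   seed = derive_seed(config$seed, 555L))
  dp_noise_seed <- if (use_dp) derive_seed(dp$seed, 999L) else NULL

  trace <- vector("list", config$rounds)
  for (t in seq_len(config$rounds)) {
    round_seed <- derive_seed(config$seed, t)
    step <- with_seed(round_seed, {
      sampled <- if (!config$with_replacement && m >= N) {
        clients_pool
      } else {
        sample_clients(clients_pool, clients_per_round = min(m, if (config$with_replacement) m else N),
                       with_replacement = config$with_replacement)
      }
      if (use_dp) {
        # dedicated noise stream so sampling and noise never interleave
        noise_fun <- function(k) with_seed(derive_seed(dp_noise_seed, t), {
          stats::rnorm(k)
        })
      }
      if (fast) {
        uc <- unique(sampled)
        D <- glm_client_deltas(params, inp$x, inp$y, rows_by_client, uc,
                               spec, opt$learning_rate)
        mult <- as.numeric(table(factor(sampled, levels = uc)))
        if (use_dp) {
          nrm <- sqrt(rowSums(D^2))
          scl <- pmin(1, dp$clip_norm / pmax(nrm, .Machine$double.eps))
          D <- D * scl
          if (dp$mode == "central") {
            agg <- drop(mult %*% D) / sum(mult)
            if (dp$noise_multiplier > 0) {
              agg <- agg + noise_fun(ncol(D)) *
                (dp$noise_multiplier * dp$clip_norm / sum(mult))
            }
          } else {
            # local DP: independent noise per sampled instance (an upload),
            # matching the per-client loop exactly
            Dins <- D[match(sampled, uc), , drop = FALSE]
            if (dp$noise_multiplier > 0) {
              nz <- matrix(noise_fun(ncol(D) * nrow(Dins)), ncol = nrow(Dins))
              Dins <- Dins + t(nz) * (dp$noise_multiplier * dp$clip_norm)
            }
            w <- sizes[sampled]
            agg <- drop((w / sum(w)) %*% Dins)
          }
        } else {
          w <- mult * sizes[uc]
          agg <- drop((w / sum(w)) %*% D)
        }
      } else {
        deltas <- vector("list", length(sampled))
        ok <- logical(length(sampled))
        for (k in seq_along(sampled)) {
          cid <- sampled[k]
          rows <- rows_by_client[[cid]]
          upd <- tryCatch(
            local_update(params,
                         list(x = inp$x[rows, , drop = FALSE], y = inp$y[rows]),
                         spec, opt, seed = derive_seed(round_seed, k)),
            error = function(e) NULL)
          if (is.null(upd)) next
          ok[k] <- TRUE
          deltas[[k]] <- upd$values - params$values
        }
        if (!any(ok)) stopf("all clients failed in round %d", t)
        deltas <- deltas[ok]
        wts <- sizes[sampled[ok]]
        if (use_dp && dp$mode == "local") {
          nz <- noise_fun(length(deltas[[1L]]) * length(deltas))
          nz <- matrix(nz, ncol = length(deltas))
          deltas <- lapply(seq_along(deltas), function(k) {
            d <- clip_update(deltas[[k]], dp$clip_norm)
            if (dp$noise_multiplier > 0) {
              d <- d + nz[, k] * (dp$noise_multiplier * dp$clip_norm)
            }
            d
          })
          agg <- aggregate_updates(deltas, wts)
        } else if (use_dp && dp$mode == "central") {
          clipped <- lapply(deltas, clip_update, S = dp$clip_norm)
          agg <- Reduce(`+`, clipped) / length(clipped)
          if (dp$noise_multiplier > 0) {
            agg <- agg + noise_fun(length(agg)) *
              (dp$noise_multiplier * dp$clip_norm / length(clipped))
          }
        } else {
          agg <- aggregate_updates(deltas, wts)
        }
      }
      list(sampled = sampled, agg = agg)
    })
    params <- new_params(params$values + config$server_lr * step$agg,
                         params$registry)
    spend <- privacy_spend(dp, q, t)
    train_loss <- as.numeric(local_loss(
      params, list(x = inp$x[split$train, , drop = FALSE],
                   y = inp$y[split$train]), spec))
    val_auc <- NA_real_
    if (length(split$test) && (t %% config$eval_every == 0L || t == config$rounds)) {
      sc <- predict_proba(params, inp$x[split$test, , drop = FALSE], spec)
      val_auc <- auc(sc, inp$y[split$test])
    }
    trace[[t]] <- data.frame(
      round = t, n_sampled = length(step$sampled),
      clients = I(list(step$sampled)),
      update_norm = sqrt(sum(step$agg^2)),
      train_loss = train_loss, val_auc = val_auc,
      eps_cum = spend$eps_cum, stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, trace)
  structure(list(params = params, trace = trace, spec = spec,
                 config = config, dp = dp, split = split,
                 n_clients = N, clients_per_round = m),
            class = "fed_train")
}

#' @export
print.fed_train <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("Federated training: %d rounds, %d/%d clients per round\n",
              nrow(x$trace), x$clients_per_round, x$n_clients))
  cat(sprintf("  final train loss %.4f", last$train_loss))
  if (!is.na(last$val_auc)) cat(sprintf(", validation AUC %.3f", last$val_auc))
  if (!is.na(last$eps_cum)) cat(sprintf(", epsilon %.3g", last$eps_cum))
  cat("\n")
  invisible(x)
}

#' Centralized baseline trainer on the pooled data
#'
#' Minimizes the identical penalized loss on the pooled cohort, either by
#' full-batch gradient descent (`method = "gd"`, the direct counterpart of
#' the federated loop) or, for unpenalized GLMs, by iteratively reweighted
#' least squares through [stats::glm.fit()] (`method = "irls"`), the
#' classical maximum-likelihood fit used as the inference anchor.
#'
#' @inheritParams run_federated_training
#' @param opt An [optimizer_config()] (gradient-descent path).
#' @param method `"gd"` or `"irls"`.
#' @param max_iter Iteration cap for gradient descent.
#' @param tol Gradient-norm convergence tolerance.
#' @return An object of class `fed_train` (single "client" holding all
#'   rows) with a `converged` flag and final `grad_norm`.
#' @export
run_centralized_training <- function(cohort, spec, opt = optimizer_config(),
                                     method = c("gd", "irls"),
                                     max_iter = 500L, tol = 1e-8,
                                     init = NULL) {
  method <- match.arg(method)
  inp <- model_inputs(cohort, spec)
  if (length(inp$y) == 0L) stopf("empty cohort")
  zv <- apply(inp$x, 2L, function(v) stats::var(v) == 0)
  if (any(zv)) {
    warning(sprintf("zero-variance feature(s) %s: model is non-identifiable",
                    paste(colnames(inp$x)[zv], collapse = ", ")),
            call. = FALSE)
  }
  if (method == "irls") {
    stopifnot(spec$kind == "glm")
    if (spec$l1 > 0 || spec$l2 > 0) {
      stopf("IRLS path fits the unpenalized likelihood; set l1 = l2 = 0")
    }
    X <- if (spec$intercept) cbind(`(Intercept)` = 1, inp$x) else inp$x
    fam <- stats::binomial(link = spec$link)
    start <- NULL
    if (spec$link == "log") {
      start <- c(log(max(mean(inp$y), 1e-3)), numeric(ncol(X) - 1L))
    }
    fit <- suppressWarnings(stats::glm.fit(X, inp$y, family = fam, start = start))
    params <- new_params(fit$coefficients, shape_registry(spec))
    trace <- data.frame(round = seq_len(fit$iter), n_sampled = 1L,
                        clients = I(as.list(rep("pooled", fit$iter))),
                        update_norm = NA_real_,
                        train_loss = NA_real_, val_auc = NA_real_,
                        eps_cum = NA_real_)
    return(structure(list(params = params, trace = trace, spec = spec,
                          converged = fit$converged, grad_norm = NA_real_,
                          method = "irls",
                          split = list(train = seq_along(inp$y), test = integer(0)),
                          n_clients = 1L, clients_per_round = 1L),
                     class = "fed_train"))
  }
  params <- init %||% default_init(spec, inp$y, seed = 1L)
  batch <- list(x = inp$x, y = inp$y)
  trace <- vector("list", max_iter)
  converged <- FALSE
  gnorm <- NA_real_
  iters <- 0L
  for (t in seq_len(max_iter)) {
    g <- local_grad(params, batch, spec)
    gnorm <- sqrt(sum(g^2))
    iters <- t
    params <- local_update(params, batch, spec, opt, seed = derive_seed(1L, t))
    trace[[t]] <- data.frame(round = t, n_sampled = 1L,
                             clients = I(list("pooled")),
                             update_norm = opt$learning_rate * gnorm,
                             train_loss = as.numeric(local_loss(params, batch, spec)),
                             val_auc = NA_real_, eps_cum = NA_real_)
    if (gnorm < tol) { converged <- TRUE; break }
  }
  if (!converged && gnorm >= tol) {
    attr(params, "note") <- sprintf(
      "gradient descent stopped after %d iterations, gradient norm %.3g",
      iters, gnorm)
  }
  structure(list(params = params, trace = do.call(rbind, trace[seq_len(iters)]),
                 spec = spec, converged = converged, grad_norm = gnorm,
                 method = "gd",
                 split = list(train = seq_along(inp$y), test = integer(0)),
                 n_clients = 1L, clients_per_round = 1L),
            class = "fed_train")
}
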