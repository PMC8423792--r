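#' Experiment configuration
#'
#' Bundles everything one of the three experiments needs: the cohort (a
#' generated `fed_cohort`, a [cohort_spec()] to generate, or a CSV path
#' with declared columns), the model formula and link, penalties, the
#' silo partition settings, the federated and DP configurations, and the
#' root seed. Configurations can also be read from a YAML or JSON file
#' whose keys mirror the argument names ([read_experiment_config()]).
#'
#' @param cohort A `fed_cohort`, `cohort_spec`, or
#'   `list(csv =, outcome =, silo =)` describing a delimited table.
#' @param formula Model formula (or a character string).
#' @param link `"logit"` or `"log"`.
#' @param l1,l2 Penalty magnitudes.
#' @param partition Optional silo settings: `list(unit = "column",
#'   column =)` or `list(unit = "dirichlet", G =, alpha =)`.
#' @param fed List of [fed_config()] arguments.
#' @param dp Optional list of [dp_config()] arguments.
#' @param experiment `"replicate"`, `"sweep"`, or `"dp_curve"`.
#' @param output_dir Optional directory for JSON/CSV reports.
#' @param seed Root seed for every stage.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, formula, link = "logit",
                              l1 = 0, l2 = 0, partition = NULL,
                              fed = list(), dp = NULL,
                              experiment = c("replicate", "sweep", "dp_curve"),
                              output_dir = NULL, seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.character(formula)) formula <- stats::as.formula(formula)
  stopifnot(inherits(formula, "formula"), link %in% c("logit", "log"))
  structure(list(cohort = cohort, formula = formula, link = link,
                 l1 = l1, l2 = l2, partition = partition,
                 fed = fed, dp = dp, experiment = experiment,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path A `.yaml`/`.yml` or `.json` configuration file.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort <- if (!is.null(cfg$cohort$csv)) {
    cfg$cohort
  } else if (!is.null(cfg$cohort_spec)) {
    deserialize_cohort_spec(cfg$cohort_spec)
  } else {
    stopf("config must provide `cohort$csv` or `cohort_spec`")
  }
  experiment_config(cohort, cfg$formula, link = cfg$link %||% "logit",
                    l1 = cfg$l1 %||% 0, l2 = cfg$l2 %||% 0,
                    partition = cfg$partition,
                    fed = cfg$fed %||% list(), dp = cfg$dp,
                    experiment = cfg$experiment %||% "replicate",
                    output_dir = cfg$output_dir, seed = cfg$seed %||% 1L)
}

resolve_cohort <- function(cfg) {
  ch <- cfg$cohort
  if (inherits(ch, "fed_cohort")) return(ch)
  if (inherits(ch, "cohort_spec")) return(generate_tabular_cohort(ch))
  if (is.list(ch) && !is.null(ch$csv)) {
    return(read_cohort_csv(ch$csv, ch$outcome, ch$silo))
  }
  stopf("cannot resolve the configured cohort")
}

resolve_fed <- function(cfg, ...) {
  fed <- cfg$fed
  if (!is.null(fed$optimizer) && !inherits(fed$optimizer, "optimizer_config")) {
    fed$optimizer <- do.call(optimizer_config, fed$optimizer)
  }
  do.call(fed_config, utils::modifyList(
    c(fed, list(seed = fed$seed %||% cfg$seed)), list(...)))
}

resolve_silo_partition <- function(cfg, cohort) {
  p <- cfg$partition
  if (is.null(p)) return(NULL)
  switch(p$unit %||% "dirichlet",
    column = partition_by_column(cohort, p$column),
    dirichlet = partition_dirichlet(cohort, p$G %||% 20L, p$alpha %||% 10,
                                    seed = p$seed %||% derive_seed(cfg$seed, 31L)),
    stopf("unknown partition unit '%s'", p$unit))
}

#' Centralized-versus-federated replication experiment
#'
#' Fits the same model three ways on the same cohort -- centralized,
#' per-patient federated, and (when silo settings are configured)
#' per-silo federated -- and reports per-feature agreement: coefficient
#' differences, confidence-interval overlap, and same-conclusion flags.
#'
#' @param cfg An [experiment_config()].
#' @return List with `fits` (named `fedglm` objects) and `agreement`
#'   (a [agreement_report()]).
#' @export
run_replication <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  cohort <- resolve_cohort(cfg)
  fedcfg <- resolve_fed(cfg, eval_split = 0)
  dp <- if (!is.null(cfg$dp)) do.call(dp_config, cfg$dp)
  fit_c <- fedglm(cfg$formula, cohort, link = cfg$link,
                  engine = "centralized", l1 = cfg$l1, l2 = cfg$l2,
                  config = fedcfg)
  fits <- list(
    centralized = fit_c,
    per_patient = fedglm(cfg$formula, cohort, link = cfg$link,
                         partition = partition_per_patient(cohort),
                         config = fedcfg, dp = dp,
                         l1 = cfg$l1, l2 = cfg$l2))
  silo <- resolve_silo_partition(cfg, cohort)
  if (!is.null(silo)) {
    fits$per_silo <- fedglm(cfg$formula, cohort, link = cfg$link,
                            partition = silo, config = fedcfg, dp = dp,
                            l1 = cfg$l1, l2 = cfg$l2)
  }
  agreement <- agreement_report(fits$centralized, fits[-1L])
  out <- list(fits = fits, agreement = agreement, seed = cfg$seed)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fits)) {
      write_report(fits[[nm]], file.path(cfg$output_dir, paste0("fit_", nm)))
    }
    write_report(agreement, file.path(cfg$output_dir, "agreement"))
  }
  out
}

#' Participation-rate sweep
#'
#' Trains one federated model per participation fraction on a shared
#' cohort and stratified 80/20 split, and reports the validation AUC and
#' its ratio to the maximum across the grid. The default grid is
#' log-spaced down to 0.1% and includes the 2% operating point at which
#' a small minority of clients suffices for near-maximal AUC.
#'
#' @param cfg An [experiment_config()].
#' @param fractions Participation fractions in (0, 1]; 1.0 is always
#'   included as the reference point.
#' @return Data frame with `fraction`, `auc`, and `auc_ratio` relative to
#'   the full-participation reference (1.0 at fraction 1 by construction).
#' @export
run_participation_sweep <- function(cfg,
                                    fractions = c(0.001, 0.002, 0.005, 0.01,
                                                  0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  stopifnot(inherits(cfg, "experiment_config"),
            all(fractions > 0), all(fractions <= 1))
  fractions <- sort(unique(c(fractions, 1)))
  cohort <- resolve_cohort(cfg)
  part <- partition_per_patient(cohort)
  aucs <- vapply(fractions, function(f) {
    fedcfg <- resolve_fed(cfg, participation = f, eval_split = 0.2)
    run <- run_federated_training(cohort, part,
                                  glm_formula_spec(cfg, cohort), fedcfg)
    va <- run$trace$val_auc
    va[max(which(!is.na(va)))]
  }, numeric(1))
  out <- data.frame(fraction = fractions, auc = aucs,
                    auc_ratio = aucs / aucs[fractions == 1])
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$output_dir, "participation_sweep.csv"),
                     row.names = FALSE)
  }
  out
}

# Build the glm_spec implied by the config formula for direct engine runs.
glm_formula_spec <- function(cfg, cohort) {
  mf <- stats::model.frame(cfg$formula, cohort_rows(cohort))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  glm_spec(setdiff(colnames(X), "(Intercept)"), link = cfg$link,
           l1 = cfg$l1, l2 = cfg$l2,
           intercept = "(Intercept)" %in% colnames(X))
}

#' Privacy-utility curve
#'
#' For each privacy budget, calibrates the noise multiplier (for central
#' DP, by inverting the multi-round accountant at the configured rounds
#' and sampling fraction; for local DP, by the classical Gaussian bound
#' per round), trains federatedly, and evaluates mean AUC over repeated
#' stratified splits. Budgets whose calibration would require a noise
#' multiplier beyond `z_max` are reported as infeasible and skipped.
#'
#' @param cfg An [experiment_config()].
#' @param budgets Epsilon budgets (> 0): cumulative for central mode,
#'   per-round for local mode.
#' @param mode `"central"` or `"local"`.
#' @param delta DP delta.
#' @param n_reps Repeated-split repetitions per budget.
#' @param z_max Feasibility cap on the calibrated noise multiplier.
#' @return Data frame with `epsilon`, `z`, `auc`, `auc_lo`, `auc_hi`,
#'   `epsilon_spent`, `feasible`.
#' @export
run_dp_curve <- function(cfg, budgets, mode = c("central", "local"),
                         delta = 1e-5, n_reps = 20L, z_max = 1e3) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "experiment_config"), all(budgets > 0))
  cohort <- resolve_cohort(cfg)
  fedcfg <- resolve_fed(cfg, eval_split = 0)
  spec <- glm_formula_spec(cfg, cohort)
  part <- partition_per_patient(cohort)
  N <- length(part$client_sizes)
  m <- fedcfg$clients_per_round %||%
    max(1L, as.integer(round((fedcfg$participation %||% 1) * N)))
  q <- min(1, m / N)

  rows <- lapply(budgets, function(eps) {
    if (mode == "local") {
      z <- calibrate_noise(eps, delta)
      spent <- gaussian_epsilon(z, delta)
    } else {
      f <- function(zz) compose_accountant(zz, q, fedcfg$rounds, delta) - eps
      z <- if (f(z_max) > 0) {
        Inf
      } else if (f(1e-3) < 0) {
        1e-3
      } else {
        stats::uniroot(f, c(1e-3, z_max), tol = 1e-6)$root
      }
      spent <- if (is.finite(z)) compose_accountant(z, q, fedcfg$rounds, delta) else NA_real_
    }
    if (!is.finite(z)) {
      return(data.frame(epsilon = eps, z = NA_real_, auc = NA_real_,
                        auc_lo = NA_real_, auc_hi = NA_real_,
                        epsilon_spent = NA_real_, feasible = FALSE))
    }
    dp <- dp_config(mode, clip_norm = cfg$dp$clip_norm %||% 1,
                    noise_multiplier = z, delta = delta,
                    seed = derive_seed(cfg$seed, round(1e3 * eps) + 7L))
    trainer <- function(train, test) {
      fit <- suppressWarnings(
        fedglm(cfg$formula, train, link = cfg$link,
               partition = partition_per_patient(train),
               config = fedcfg, dp = dp, l1 = cfg$l1, l2 = cfg$l2))
      predict(fit, test)
    }
    ev <- repeated_split_evaluate(cohort, trainer, n_reps = n_reps,
                                  seed = derive_seed(cfg$seed, 17L))
    data.frame(epsilon = eps, z = z, auc = ev$mean_auc,
               auc_lo = ev$ci[1L], auc_hi = ev$ci[2L],
               epsilon_spent = spent, feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$output_dir,
                                    paste0("dp_curve_", mode, ".csv")),
                     row.names = FALSE)
  }
  out
}
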