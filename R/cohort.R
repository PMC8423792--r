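#' Specify a synthetic tabular cohort
#'
#' A `cohort_spec` fixes everything needed to generate a binary-outcome
#' cohort with known truth: sample size, covariate distributions, the true
#' coefficient vector on the linear-predictor scale (log-odds for the logit
#' link, log-risk for the log link), an optional cluster structure, and the
#' RNG seed. `beta` has one entry per design column plus an intercept, in
#' the order `(intercept, covariate columns...)` with categorical
#' covariates expanded to reference-coded indicators.
#'
#' @param n Number of patients (>= 1).
#' @param covariates List of [covariate_spec()] objects.
#' @param beta True coefficient vector, intercept first; its length must be
#'   `1 + ` the number of design columns.
#' @param link `"logit"` (odds-ratio scale) or `"log"` (risk-ratio scale).
#' @param clusters Optional `list(G =, sigma_u =, treatment_at_cluster =)`
#'   describing `G` clusters with a Normal(0, `sigma_u`^2) random intercept
#'   on the linear-predictor scale. When `treatment_at_cluster` is `TRUE`,
#'   the binary covariate named `"treatment"` is randomized per cluster
#'   (cluster-randomized-trial design) rather than per patient.
#' @param seed RNG seed; the whole cohort is drawn from a single stream
#'   seeded once, so identical specs give bit-identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_tabular_cohort()], [generate_cluster_trial()]
#' @export
cohort_spec <- function(n, covariates, beta,
                        link = c("logit", "log"),
                        clusters = NULL, seed = 1L) {
  link <- match.arg(link)
  if (!is_count(n)) stopf("n must be a positive integer")
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  stopifnot(length(covariates) >= 1L,
            all(vapply(covariates, inherits, TRUE, "covariate_spec")))
  p <- sum(vapply(covariates, n_design_cols, integer(1)))
  if (length(beta) != p + 1L) {
    stopf("beta has length %d but the design has %d columns plus intercept",
          length(beta), p)
  }
  if (!is.null(clusters)) {
    stopifnot(is.list(clusters))
    clusters$G <- clusters$G %||% 2L
    clusters$sigma_u <- clusters$sigma_u %||% 0
    clusters$treatment_at_cluster <- isTRUE(clusters$treatment_at_cluster)
    if (!is_count(clusters$G, min = 1)) stopf("clusters$G must be >= 1")
    if (clusters$G > n) stopf("clusters$G (%d) exceeds n (%d)", clusters$G, n)
    if (clusters$sigma_u < 0) stopf("clusters$sigma_u must be >= 0")
    if (clusters$treatment_at_cluster) {
      nm <- vapply(covariates, `[[`, "", "name")
      kd <- vapply(covariates, `[[`, "", "kind")
      if (!any(nm == "treatment" & kd == "binary")) {
        stopf("treatment_at_cluster requires a binary covariate named 'treatment'")
      }
    }
  }
  structure(list(n = as.integer(n), covariates = covariates,
                 beta = as.numeric(beta), link = link,
                 clusters = clusters, seed = as.integer(seed)),
            class = "cohort_spec")
}

design_names <- function(spec) {
  unlist(lapply(spec$covariates, design_col_names), use.names = FALSE)
}

linkinv <- function(eta, link) {
  switch(link, logit = sigmoid(eta), log = exp(eta))
}

#' Generate a tabular binary-outcome cohort with known coefficients
#'
#' Draws covariates from the spec's marginals, forms the linear predictor
#' `eta = x %*% beta` (plus a per-cluster random intercept if a cluster
#' structure is given), and draws outcomes `Bernoulli(linkinv(eta))`.
#' For the log link the realized per-row probabilities are validated:
#' a spec whose draws produce a probability above 1 is rejected with a
#' diagnostic naming the covariate driving the violation, rather than
#' silently truncated.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `fed_cohort`: a list with `data` (data frame
#'   with `patient_id`, raw covariates, `outcome`, and `cluster_id` when
#'   clustered) and the generating `spec` as provenance.
#' @examples
#' spec <- cohort_spec(
#'   n = 500,
#'   covariates = list(
#'     covariate_spec("age", "continuous", mean = 0, sd = 1),
#'     covariate_spec("female", "binary", prevalence = 0.5)
#'   ),
#'   beta = c(-1, 0.5, -1.05), link = "logit", seed = 7
#' )
#' coh <- generate_tabular_cohort(spec)
#' mean(coh$data$outcome)
#' @export
generate_tabular_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    df <- as.data.frame(lapply(spec$covariates, draw_covariate, n = spec$n),
                        col.names = vapply(spec$covariates, `[[`, "", "name"))
    cluster_id <- NULL
    u <- 0
    if (!is.null(spec$clusters)) {
      cl <- spec$clusters
      # round-robin base assignment then shuffle: every cluster non-empty
      cluster_id <- sample(rep_len(seq_len(cl$G), spec$n))
      if (cl$treatment_at_cluster) {
        cv <- spec$covariates[[which(vapply(spec$covariates, `[[`, "", "name") == "treatment")]]
        arm <- stats::rbinom(cl$G, 1L, cv$params$prevalence)
        df$treatment <- arm[cluster_id]
      }
      ug <- stats::rnorm(cl$G, 0, cl$sigma_u)
      u <- ug[cluster_id]
    }
    X <- expand_design(df, spec$covariates)
    eta <- drop(spec$beta[1L] + X %*% spec$beta[-1L]) + u
    p <- linkinv(eta, spec$link)
    if (spec$link == "log" && any(p > 1)) {
      bad <- which.max(eta)
      contrib <- c(0, X[bad, ] * spec$beta[-1L])
      worst <- design_names(spec)[which.max(abs(contrib[-1L]))]
      stopf(paste0(
        "log-link spec produces row probabilities > 1 ",
        "(max linear predictor %.3f at row %d; largest contribution from ",
        "covariate column '%s'); shrink beta or center that covariate"),
        max(eta), bad, worst)
    }
    y <- stats::rbinom(spec$n, 1L, pmin(p, 1))
    out <- data.frame(patient_id = seq_len(spec$n), df,
                      outcome = y, check.names = FALSE)
    if (!is.null(cluster_id)) out$cluster_id <- cluster_id
    structure(list(data = out, spec = spec), class = "fed_cohort")
  })
}

#' Generate a cluster-randomized-trial cohort
#'
#' Convenience wrapper around [generate_tabular_cohort()] for specs with a
#' cluster structure and cluster-level treatment assignment: patients are
#' spread over `G` communities, the binary `treatment` covariate is
#' constant within each community, and outcomes include a per-community
#' random intercept of standard deviation `sigma_u` on the linear-predictor
#' scale. With a log link the generated coefficient on `treatment` is a
#' log risk ratio, the endpoint of cluster-randomized trials analysed with
#' a binomial GLM and cluster-robust standard errors.
#'
#' @param spec A [cohort_spec()] with `clusters$treatment_at_cluster = TRUE`
#'   and `clusters$G >= 2`.
#' @return A `fed_cohort` whose `data` carries `cluster_id`.
#' @export
generate_cluster_trial <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(spec$clusters) || !spec$clusters$treatment_at_cluster) {
    stopf("spec must set clusters$treatment_at_cluster = TRUE")
  }
  if (spec$clusters$G < 2L) stopf("a trial needs G >= 2 clusters")
  generate_tabular_cohort(spec)
}

#' @export
print.fed_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("Synthetic cohort: %d patients, %d covariates, %s link\n",
              nrow(d), length(x$spec$covariates), x$spec$link))
  cat(sprintf("  outcome prevalence %.3f", mean(d$outcome)))
  if (!is.null(d$cluster_id)) {
    cat(sprintf("; %d clusters", length(unique(d$cluster_id))))
  }
  cat(sprintf("; seed %d\n", x$spec$seed))
  invisible(x)
}

# Design matrix (no intercept column) for a generated cohort.
cohort_design <- function(cohort) {
  expand_design(cohort$data, cohort$spec$covariates)
}

#' Write / read a cohort as delimited text with a JSON provenance sidecar
#'
#' `write_cohort()` writes `<path>.csv` (header row, UTF-8, "." decimal)
#' and `<path>.json` holding the generating spec and seed;
#' `read_cohort()` reads the pair back. `read_cohort_csv()` ingests a
#' user-supplied table with declared outcome (and optional silo) columns,
#' for users who have downloaded a public study dataset themselves.
#'
#' @param cohort A `fed_cohort`.
#' @param path File stem (without extension).
#' @return `write_cohort()` returns `path` invisibly; the readers return a
#'   `fed_cohort` (for `read_cohort_csv()`, with a minimal provenance
#'   record and `spec = NULL`).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fed_cohort"))
  utils::write.csv(cohort$data, paste0(path, ".csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(serialize_cohort_spec(cohort$spec),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(paste0(path, ".csv"), fileEncoding = "UTF-8")
  spec <- deserialize_cohort_spec(jsonlite::read_json(paste0(path, ".json")))
  for (cv in spec$covariates) {
    if (cv$kind == "categorical") {
      d[[cv$name]] <- factor(d[[cv$name]], levels = cv$params$levels)
    }
  }
  structure(list(data = d, spec = spec), class = "fed_cohort")
}

#' @rdname write_cohort
#' @param file Path of an existing CSV, one row per patient.
#' @param outcome Name of the binary outcome column.
#' @param silo Optional name of a natural-silo (grouping) column.
#' @export
read_cohort_csv <- function(file, outcome, silo = NULL) {
  d <- utils::read.csv(file, fileEncoding = "UTF-8")
  if (!outcome %in% names(d)) stopf("outcome column '%s' not found", outcome)
  if (!all(d[[outcome]] %in% c(0, 1))) {
    stopf("outcome column '%s' must be coded 0/1", outcome)
  }
  if (!is.null(silo) && !silo %in% names(d)) {
    stopf("silo column '%s' not found", silo)
  }
  names(d)[names(d) == outcome] <- "outcome"
  if (!"patient_id" %in% names(d)) d$patient_id <- seq_len(nrow(d))
  structure(list(data = d, spec = NULL, silo = silo), class = "fed_cohort")
}

serialize_cohort_spec <- function(spec) {
  list(
    n = spec$n, link = spec$link, beta = spec$beta, seed = spec$seed,
    clusters = spec$clusters,
    covariates = lapply(spec$covariates, unclass)
  )
}

deserialize_cohort_spec <- function(js) {
  covs <- lapply(js$covariates, function(cv) {
    p <- cv$params
    switch(cv$kind,
      continuous = covariate_spec(cv$name, "continuous",
                                  mean = p$mean, sd = p$sd),
      binary = covariate_spec(cv$name, "binary", prevalence = p$prevalence),
      categorical = covariate_spec(cv$name, "categorical",
                                   levels = unlist(p$levels),
                                   probs = unlist(p$probs))
    )
  })
  cohort_spec(js$n, covs, unlist(js$beta), link = js$link,
              clusters = if (!is.null(js$clusters)) {
                list(G = js$clusters$G, sigma_u = js$clusters$sigma_u,
                     treatment_at_cluster = isTRUE(js$clusters$treatment_at_cluster))
              },
              seed = js$seed)
}
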