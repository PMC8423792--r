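#' Describe one covariate of a synthetic cohort
#'
#' A `covariate_spec` describes the marginal distribution of a single
#' patient-level covariate: a Normal continuous measurement, a Bernoulli
#' indicator, or a categorical factor with stated level probabilities.
#' Categorical covariates are expanded to reference-coded indicator columns
#' in the design matrix; the reference level is the first listed category,
#' matching how odds ratios are conventionally reported per level.
#'
#' @param name Column name in the generated cohort.
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param mean,sd Normal parameters (continuous only); `sd` must be > 0.
#' @param prevalence Success probability in `[0, 1]` (binary only).
#' @param levels Category labels (categorical only).
#' @param probs Category probabilities; non-negative, summing to 1.
#'
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("age", "continuous", mean = 60, sd = 10)
#' covariate_spec("female", "binary", prevalence = 0.45)
#' covariate_spec("cancer", "categorical",
#'   levels = c("never", "former", "recent"), probs = c(0.9, 0.07, 0.03))
#' @export
covariate_spec <- function(name,
                           kind = c("continuous", "binary", "categorical"),
                           mean = 0, sd = 1,
                           prevalence = 0.5,
                           levels = NULL, probs = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (!is.numeric(sd) || length(sd) != 1L || !(sd > 0)) {
      stopf("covariate '%s': sd must be a single value > 0", name)
    }
    params <- list(mean = mean, sd = sd)
  } else if (kind == "binary") {
    if (!is_prob(prevalence)) {
      stopf("covariate '%s': prevalence must lie in [0, 1]", name)
    }
    params <- list(prevalence = prevalence)
  } else {
    if (is.null(levels) || length(levels) < 2L) {
      stopf("covariate '%s': categorical needs >= 2 levels", name)
    }
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels) || any(probs < 0) || any(probs > 1) ||
        abs(sum(probs) - 1) > 1e-8) {
      stopf("covariate '%s': probs must be in [0,1] and sum to 1", name)
    }
    params <- list(levels = as.character(levels), probs = probs)
  }
  structure(list(name = name, kind = kind, params = params),
            class = "covariate_spec")
}

# Number of design-matrix columns a covariate expands to.
n_design_cols <- function(cv) {
  switch(cv$kind,
    continuous = 1L,
    binary = 1L,
    categorical = length(cv$params$levels) - 1L
  )
}

design_col_names <- function(cv) {
  switch(cv$kind,
    continuous = cv$name,
    binary = cv$name,
    categorical = paste0(cv$name, cv$params$levels[-1L])
  )
}

# Draw n values of one covariate from the current RNG stream.
draw_covariate <- function(cv, n) {
  switch(cv$kind,
    continuous = stats::rnorm(n, cv$params$mean, cv$params$sd),
    binary = stats::rbinom(n, 1L, cv$params$prevalence),
    categorical = factor(
      sample(cv$params$levels, n, replace = TRUE, prob = cv$params$probs),
      levels = cv$params$levels
    )
  )
}

# Expand raw covariate columns into the (reference-coded) design matrix,
# without intercept. `covariates` is the list of covariate_spec objects.
expand_design <- function(df, covariates) {
  cols <- lapply(covariates, function(cv) {
    x <- df[[cv$name]]
    if (cv$kind == "categorical") {
      lv <- cv$params$levels
      m <- vapply(lv[-1L], function(l) as.numeric(x == l), numeric(nrow(df)))
      m <- matrix(m, nrow = nrow(df),
                  dimnames = list(NULL, design_col_names(cv)))
      m
    } else {
      matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, cv$name))
    }
  })
  do.call(cbind, cols)
}
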