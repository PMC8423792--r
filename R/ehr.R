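#' Specify an EHR-like token-sequence cohort
#'
#' Emulates the statistical shape of an electronic-health-record mortality
#' task: each patient carries a multiset of note/code tokens of variable
#' length plus a few demographic covariates, and a binary label (e.g.
#' in-hospital mortality). Tokens are drawn from a small number of latent
#' topics: each topic is a categorical distribution over the vocabulary,
#' each patient has Dirichlet topic weights, and the label depends on those
#' latent weights and on the demographics through a logistic model. The
#' label therefore carries real signal about token content -- what an
#' embedding classifier must recover -- without imitating any real EHR
#' schema.
#'
#' @param n Number of patients.
#' @param vocab_size Token vocabulary size (>= 1).
#' @param length_dist `list(dist = "poisson", lambda =)` or
#'   `list(dist = "nbinom", mu =, size =)` for per-patient token counts.
#' @param demographics List of [covariate_spec()] (possibly empty).
#' @param label_model `list(intercept =, topic =, demo =)`: logistic
#'   coefficients on the intercept, the patient's latent topic-weight
#'   vector (its length sets the number of topics), and the demographic
#'   design columns (may be `NULL` when there are none).
#' @param topic_concentration Dirichlet concentration of per-topic token
#'   distributions (small values give sparse, well-separated topics).
#' @param seed RNG seed; one stream drives the whole cohort.
#'
#' @return An object of class `ehr_cohort_spec`.
#' @export
ehr_cohort_spec <- function(n, vocab_size,
                            length_dist = list(dist = "poisson", lambda = 20),
                            demographics = list(),
                            label_model = list(intercept = -2, topic = c(1, -1),
                                               demo = NULL),
                            topic_concentration = 0.3,
                            seed = 1L) {
  if (!is_count(n)) stopf("n must be a positive integer")
  if (!is_count(vocab_size)) stopf("vocab_size must be >= 1")
  stopifnot(is.list(length_dist), length_dist$dist %in% c("poisson", "nbinom"))
  if (length(demographics) &&
      !all(vapply(demographics, inherits, TRUE, "covariate_spec"))) {
    stopf("demographics must be covariate_spec objects")
  }
  K <- length(label_model$topic)
  if (K < 1L) stopf("label_model$topic needs >= 1 topic coefficient")
  p_demo <- sum(vapply(demographics, n_design_cols, integer(1)))
  nd <- length(label_model$demo %||% numeric(0))
  if (nd != p_demo) {
    stopf("label_model$demo has length %d but demographics expand to %d columns",
          nd, p_demo)
  }
  structure(list(n = as.integer(n), vocab_size = as.integer(vocab_size),
                 length_dist = length_dist, demographics = demographics,
                 label_model = label_model,
                 topic_concentration = topic_concentration,
                 n_topics = K, seed = as.integer(seed)),
            class = "ehr_cohort_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Generate an EHR-like cohort of token multisets with binary labels
#'
#' @param spec An [ehr_cohort_spec()].
#' @return An object of class `ehr_cohort`: `data` (patient_id,
#'   demographics, `n_tokens`, `outcome`), `tokens` (list of integer token
#'   vectors, one multiset per patient), and the `spec`.
#' @seealso [token_matrix()] to obtain the patient-by-vocabulary count
#'   matrix an embedding model consumes.
#' @export
generate_ehr_cohort <- function(spec) {
  stopifnot(inherits(spec, "ehr_cohort_spec"))
  with_seed(spec$seed, {
    K <- spec$n_topics
    V <- spec$vocab_size
    # per-topic token distributions
    phi <- t(vapply(seq_len(K),
                    function(k) rdirichlet1(rep(spec$topic_concentration, V)),
                    numeric(V)))
    phi <- matrix(phi, nrow = K)
    theta <- t(vapply(seq_len(spec$n), function(i) rdirichlet1(rep(1, K)),
                      numeric(K)))
    theta <- matrix(theta, ncol = K)
    L <- switch(spec$length_dist$dist,
      poisson = stats::rpois(spec$n, spec$length_dist$lambda),
      nbinom = stats::rnbinom(spec$n, mu = spec$length_dist$mu,
                              size = spec$length_dist$size))
    tokens <- lapply(seq_len(spec$n), function(i) {
      if (L[i] == 0L) return(integer(0))
      pr <- drop(theta[i, , drop = FALSE] %*% phi)
      sort(sample.int(V, L[i], replace = TRUE, prob = pr))
    })
    if (length(spec$demographics)) {
      demo <- as.data.frame(lapply(spec$demographics, draw_covariate, n = spec$n),
                            col.names = vapply(spec$demographics, `[[`, "", "name"))
      Xd <- expand_design(demo, spec$demographics)
    } else {
      demo <- NULL
      Xd <- matrix(0, spec$n, 0)
    }
    lm_ <- spec$label_model
    eta <- lm_$intercept + drop(theta %*% lm_$topic)
    if (ncol(Xd)) eta <- eta + drop(Xd %*% lm_$demo)
    y <- stats::rbinom(spec$n, 1L, sigmoid(eta))
    d <- data.frame(patient_id = seq_len(spec$n))
    if (!is.null(demo)) d <- cbind(d, demo)
    d$n_tokens <- L
    d$outcome <- y
    structure(list(data = d, tokens = tokens, spec = spec),
              class = "ehr_cohort")
  })
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "EHR-like cohort: %d patients, vocab %d, median %d tokens/patient, prevalence %.3f\n",
    nrow(x$data), x$spec$vocab_size, stats::median(x$data$n_tokens),
    mean(x$data$outcome)))
  invisible(x)
}

#' Patient-by-vocabulary token count matrix
#'
#' @param cohort An `ehr_cohort`.
#' @return An `n x vocab_size` dense count matrix (rows are patients).
#' @export
token_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  V <- cohort$spec$vocab_size
  n <- length(cohort$tokens)
  M <- matrix(0, n, V)
  for (i in seq_len(n)) {
    tk <- cohort$tokens[[i]]
    if (length(tk)) {
      tb <- tabulate(tk, nbins = V)
      M[i, ] <- tb
    }
  }
  M
}
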