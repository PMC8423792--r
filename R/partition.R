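#' Units of federation: partition objects
#'
#' A partition maps every patient of a cohort to a client (unit of
#' federation). Three constructions cover the cross-device / cross-silo
#' spectrum: one client per patient ([partition_per_patient()]), natural
#' silos given by a grouping column such as hospital or country
#' ([partition_by_column()]), and random silos of heterogeneous size drawn
#' from a Dirichlet distribution ([partition_dirichlet()]).
#'
#' @name fed_partition
#' @return All partitioners return an object of class `fed_partition`:
#'   `unit` (construction used), `assignment` (data frame `patient_id`,
#'   `client_id`), `client_sizes` (named integer vector of row counts,
#'   every client >= 1), and `params` for the Dirichlet case.
NULL

new_partition <- function(unit, patient_id, client_id, params = NULL) {
  ord <- order(patient_id)
  assignment <- data.frame(patient_id = patient_id[ord],
                           client_id = as.character(client_id)[ord],
                           stringsAsFactors = FALSE)
  sizes <- table(assignment$client_id)
  client_sizes <- stats::setNames(as.integer(sizes), names(sizes))
  structure(list(unit = unit, assignment = assignment,
                 client_sizes = client_sizes, params = params),
            class = "fed_partition")
}

#' @export
print.fed_partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d clients over %d rows; sizes [%d, %d]\n",
              x$unit, length(x$client_sizes), nrow(x$assignment),
              min(x$client_sizes), max(x$client_sizes)))
  invisible(x)
}

cohort_rows <- function(cohort) {
  if (inherits(cohort, c("fed_cohort", "ehr_cohort"))) cohort$data else cohort
}

#' @describeIn fed_partition one client per distinct patient (cross-device
#'   extreme); a patient contributing several rows keeps them all on one
#'   client.
#' @param cohort A `fed_cohort`, `ehr_cohort`, or data frame with a
#'   `patient_id` column.
#' @export
partition_per_patient <- function(cohort) {
  d <- cohort_rows(cohort)
  if (is.null(d) || nrow(d) == 0L) stopf("cannot partition an empty cohort")
  new_partition("per_patient", d$patient_id, as.character(d$patient_id))
}

#' @describeIn fed_partition natural silos: one client per distinct value
#'   of `column` (e.g. country, hospital unit, community).
#' @param column Name of the grouping column.
#' @export
partition_by_column <- function(cohort, column) {
  d <- cohort_rows(cohort)
  if (is.null(d) || nrow(d) == 0L) stopf("cannot partition an empty cohort")
  if (!column %in% names(d)) stopf("column '%s' not found in cohort", column)
  v <- d[[column]]
  if (anyNA(v)) {
    stopf("missing silo label in column '%s' for patient_id %s",
          column, paste(utils::head(d$patient_id[is.na(v)], 5L), collapse = ", "))
  }
  new_partition("natural", d$patient_id, as.character(v))
}

#' @describeIn fed_partition Dirichlet random silos: draw group proportions
#'   `p ~ Dirichlet(alpha * 1_G)`, then assign each patient independently
#'   to group `g` with probability `p_g`. Small `alpha` yields highly
#'   unequal silo sizes; `alpha -> Inf` approaches equal silos. Groups
#'   that receive no patient are dropped (the sampling law is kept exact,
#'   so the realized client count can be below `G`).
#' @param G Number of groups drawn (>= 1).
#' @param alpha Dirichlet concentration (> 0).
#' @param seed RNG seed for the proportions and assignments.
#' @export
partition_dirichlet <- function(cohort, G, alpha, seed = 1L) {
  d <- cohort_rows(cohort)
  if (is.null(d) || nrow(d) == 0L) stopf("cannot partition an empty cohort")
  if (!is_count(G)) stopf("G must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0) stopf("alpha must be > 0")
  pid <- unique(d$patient_id)
  with_seed(seed, {
    p <- rdirichlet1(rep(alpha, G))
    g <- sample.int(G, length(pid), replace = TRUE, prob = p)
  })
  map <- stats::setNames(g, pid)
  cl <- sprintf("silo_%02d", map[as.character(d$patient_id)])
  new_partition("dirichlet", d$patient_id, cl,
                params = list(G = as.integer(G), alpha = alpha,
                              seed = as.integer(seed)))
}

# Row indices held by each client, in client_sizes order.
client_row_index <- function(partition, patient_id) {
  cl <- partition$assignment$client_id[
    match(patient_id, partition$assignment$patient_id)]
  split(seq_along(patient_id), cl)
}

#' Write / read a partition as CSV plus JSON parameter sidecar
#'
#' @param partition A `fed_partition`.
#' @param path File stem (writes `<path>.csv` and `<path>.json`).
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a `fed_partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "fed_partition"))
  utils::write.csv(partition$assignment, paste0(path, ".csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(unit = partition$unit, params = partition$params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  a <- utils::read.csv(paste0(path, ".csv"), fileEncoding = "UTF-8",
                       colClasses = c(client_id = "character"))
  js <- jsonlite::read_json(paste0(path, ".json"))
  new_partition(js$unit, a$patient_id, a$client_id,
                params = if (!is.null(js$params)) {
                  list(G = js$params$G, alpha = js$params$alpha,
                       seed = js$params$seed)
                })
}
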