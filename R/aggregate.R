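#' Aggregate one subject's accepted stance events
#'
#' Pools accepted events from both feet: the subject's mean curve is the
#' arithmetic mean of every data point at the same normalized time index
#' (0-99), and each curve parameter is averaged over the accepted,
#' non-degenerate events.
#'
#' @param curves list of `normalized_stance` objects for the accepted
#'   events of one subject.
#' @param params list of `stance_parameters` (same events, same order).
#' @param rejections optional list of `stance_rejection` objects (or a
#'   plain count) folded into `n_events_rejected`.
#' @return object of class `subject_aggregate`: `subject_id`,
#'   `mean_curve` (length 100), `n_steps_accepted`, `n_events_rejected`,
#'   and `parameter_means` (named numeric, nine parameters). Returns
#'   `NULL` with a warning when no event survives.
#' @export
aggregate_subject <- function(curves, params, rejections = list()) {
  stopifnot(length(curves) == length(params))
  keep <- vapply(params, function(p) !isTRUE(p$degenerate), logical(1))
  n_prior <- if (is.numeric(rejections)) rejections else length(rejections)
  n_rej <- n_prior + sum(!keep)
  curves <- curves[keep]
  params <- params[keep]
  if (length(curves) == 0) {
    warning("subject has no accepted stance events; excluded")
    return(NULL)
  }
  sid <- curves[[1]]$subject_id
  ids <- vapply(curves, function(x) x$subject_id, character(1))
  if (!all(ids == sid)) stop("events from multiple subjects passed together")
  mat <- vapply(curves, function(x) x$values, numeric(100))
  pm <- vapply(PARAM_COLUMNS, function(cn) {
    mean(vapply(params, function(p) p[[cn]], numeric(1)))
  }, numeric(1))
  structure(list(subject_id = sid,
                 mean_curve = rowMeans(mat),
                 n_steps_accepted = length(curves),
                 n_events_rejected = n_rej,
                 parameter_means = pm),
            class = "subject_aggregate")
}

#' @export
print.subject_aggregate <- function(x, ...) {
  cat(sprintf("<subject_aggregate> %s: %d steps accepted, %d events rejected\n",
              x$subject_id, x$n_steps_accepted, x$n_events_rejected))
  print(round(x$parameter_means, 3))
  invisible(x)
}

#' Export normalized stance curves as a 100-column matrix CSV
#'
#' One row per curve: `subject_id`, `side`, then `v0` ... `v99` (% body
#' weight at each percent of stance duration). Accepts a list of
#' `normalized_stance` objects or of `subject_aggregate`s (whose mean
#' curves are written with side `"both"`).
#'
#' @param curves list of `normalized_stance` or `subject_aggregate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_matrix <- function(curves, path) {
  rows <- lapply(curves, function(x) {
    if (inherits(x, "subject_aggregate"))
      c(x$subject_id, "both", sprintf("%.9g", x$mean_curve))
    else
      c(x$subject_id, x$side, sprintf("%.9g", x$values))
  })
  header <- c("subject_id", "side", paste0("v", 0:99))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, character(1), collapse = ",")), con)
  invisible(path)
}

#' Group mean curves with pointwise 95% confidence bands
#'
#' Splits subject aggregates into two groups and computes, per normalized
#' time index, each group's mean curve and the t-based 95% confidence
#' interval `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param aggregates list of `subject_aggregate` objects.
#' @param split logical vector (length = number of aggregates): `TRUE`
#'   for group A, `FALSE` for group B.
#' @param conf confidence level (default 0.95).
#' @return list of two elements (`A`, `B`), each with `n`, `mean`,
#'   `lower`, `upper` (length-100 vectors). For a group of size 1 the
#'   band is `NA` and a flag `ci_defined = FALSE` is set.
#' @export
group_curve_band <- function(aggregates, split, conf = 0.95) {
  stopifnot(length(split) == length(aggregates), !anyNA(split))
  if (!any(split) || !any(!split)) stop("both groups must be non-empty")
  band <- function(members) {
    mat <- vapply(members, function(a) a$mean_curve, numeric(100))
    mat <- matrix(mat, nrow = 100)
    n <- ncol(mat)
    m <- rowMeans(mat)
    if (n < 2)
      return(list(n = n, mean = m, lower = rep(NA_real_, 100),
                  upper = rep(NA_real_, 100), ci_defined = FALSE))
    s <- apply(mat, 1, stats::sd)
    hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
    list(n = n, mean = m, lower = m - hw, upper = m + hw, ci_defined = TRUE)
  }
  list(A = band(aggregates[split]), B = band(aggregates[!split]))
}
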