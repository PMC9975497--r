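#' Convert raw Newton readings to percent body weight
#'
#' Divides each force sample by the subject's static weight force
#' (mass x g) and expresses the result in percent. Because the insole
#' measures dynamic ground reaction force rather than weight, peak values
#' routinely exceed 100 % BW. Missing samples stay missing; they are
#' bridged later by the spline.
#'
#' @param event a `stance_event` (or any numeric force vector in N).
#' @param profile one-row subject profile (needs `weight` in kg), or a
#'   numeric weight.
#' @param g gravitational acceleration in m/s^2.
#' @return numeric vector of force in % body weight, `NA` preserved.
#' @export
normalize_force <- function(event, profile, g = 9.81) {
  f <- if (inherits(event, "stance_event")) event$raw_force else as.numeric(event)
  w <- if (is.numeric(profile)) profile else profile$weight
  if (is.null(w) || length(w) != 1 || is.na(w) || w <= 0)
    stop("subject weight must be a single positive value (kg)")
  f / (w * g) * 100
}

#' Rejection marker for events that cannot be processed
#'
#' @param rule short machine-readable reason code.
#' @param detail optional human-readable detail.
#' @return object of class `stance_rejection`.
#' @export
stance_rejection <- function(rule, detail = NULL) {
  structure(list(rule = rule, detail = detail), class = "stance_rejection")
}

#' Test for a rejection marker
#' @param x any object.
#' @return `TRUE` if `x` is a `stance_rejection`.
#' @export
is_rejection <- function(x) inherits(x, "stance_rejection")

#' @export
print.stance_rejection <- function(x, ...) {
  cat(sprintf("<stance_rejection> %s%s\n", x$rule,
              if (is.null(x$detail)) "" else paste0(": ", x$detail)))
  invisible(x)
}

#' Time-normalize a stance event to 100 samples
#'
#' Fits a natural cubic spline (zero second derivative at both boundary
#' knots) to the non-missing `(timestamp, force)` pairs and evaluates it
#' at 100 equidistant time points spanning `[t_first, t_last]` inclusive,
#' so normalized index i (0-99) sits at i/99 of the stance duration.
#' Negative spline overshoots are clipped to 0 % BW since negative
#' vertical ground reaction force is unphysical.
#'
#' @param bw_values force in % body weight at the event's timestamps
#'   (`NA` = missing), as returned by [normalize_force()].
#' @param timestamps the event's sample timestamps (ms).
#' @param subject_id,side provenance carried into the result.
#' @return `normalized_stance` object (fields `values` of length 100,
#'   `source_duration` in ms), or a [stance_rejection()] with rule
#'   `"too_few_knots"` when fewer than 4 non-missing samples exist.
#' @export
time_normalize <- function(bw_values, timestamps, subject_id = NA_character_,
                           side = NA_character_) {
  ok <- !is.na(bw_values)
  if (sum(ok) < 4)
    return(stance_rejection("too_few_knots",
                            sprintf("%d non-missing samples", sum(ok))))
  x <- timestamps[ok]
  y <- bw_values[ok]
  xout <- seq(timestamps[1], timestamps[length(timestamps)], length.out = 100)
  v <- stats::spline(x, y, xout = xout, method = "natural")$y
  v[v < 0] <- 0
  structure(list(subject_id = subject_id, side = side, values = v,
                 source_duration = timestamps[length(timestamps)] - timestamps[1]),
            class = "normalized_stance")
}

#' Normalize a stance event on both axes
#'
#' Convenience wrapper: [normalize_force()] followed by
#' [time_normalize()].
#'
#' @inheritParams normalize_force
#' @return `normalized_stance` or `stance_rejection`.
#' @export
normalize_stance <- function(event, profile, g = 9.81) {
  stopifnot(inherits(event, "stance_event"))
  bw <- normalize_force(event, profile, g)
  time_normalize(bw, event$timestamps, event$subject_id, event$side)
}

#' @export
print.normalized_stance <- function(x, ...) {
  cat(sprintf("<normalized_stance> subject %s (%s), %0.f ms source, peak %.1f %%BW\n",
              x$subject_id, x$side, x$source_duration, max(x$values)))
  invisible(x)
}
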