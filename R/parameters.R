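#' Compute the nine stance-phase curve parameters
#'
#' Given a 100-point normalized curve and its disambiguated extrema,
#' computes four section means, the three extremum forces, and the
#' loading/unloading slopes. All index ranges are inclusive on both ends
#' (boundary samples are shared between adjacent sections); one
#' normalized index equals 1 % of stance duration, so slopes carry units
#' of % body weight per % stance phase duration.
#'
#' Sections: loading = start of stance to Fz2, mid = Fz2 to Fz4,
#' unloading = Fz4 to end of stance. The loading slope is the secant from
#' index 0 to the first sample at or above 80 % of Fz2; the unloading
#' slope is the secant from the first sample after Fz4 below 80 % of Fz4
#' to index 99. Events where either 80 %-crossing collapses the
#' denominator (crossing at index 0, at index 99, or not present) are
#' flagged `degenerate` and excluded from aggregation.
#'
#' @param ns `normalized_stance` (or bare 100-point curve).
#' @param ext `stance_extrema` for the same curve.
#' @return object of class `stance_parameters`: fields `fmean_stance`,
#'   `fmean_load`, `fmean_mid`, `fmean_unload`, `fz2`, `fz3`, `fz4`
#'   (% BW), `loading_slope`, `unloading_slope` (% BW / % stance), and a
#'   logical `degenerate` flag.
#' @export
compute_parameters <- function(ns, ext) {
  v <- if (inherits(ns, "normalized_stance")) ns$values else as.numeric(ns)
  stopifnot(length(v) == 100, inherits(ext, "stance_extrema"))
  i2 <- ext$i_fz2; i4 <- ext$i_fz4   # 0-based

  fmean_stance <- mean(v)
  fmean_load <- mean(v[1:(i2 + 1)])
  fmean_mid <- mean(v[(i2 + 1):(i4 + 1)])
  fmean_unload <- mean(v[(i4 + 1):100])

  degenerate <- FALSE
  # loading slope: first sample at or above 80% of Fz2
  i80 <- which(v >= 0.8 * ext$fz2)[1] - 1L
  if (is.na(i80) || i80 == 0L) {
    loading_slope <- NA_real_
    degenerate <- TRUE
  } else {
    loading_slope <- (v[i80 + 1L] - v[1]) / i80
  }
  # unloading slope: first sample strictly after Fz4 below 80% of Fz4
  tail_idx <- if (i4 + 2L <= 100L) (i4 + 2L):100L else integer(0)
  hit <- tail_idx[v[tail_idx] < 0.8 * ext$fz4][1]
  j80 <- if (length(hit) == 0 || is.na(hit)) NA_integer_ else hit - 1L
  if (is.na(j80) || j80 == 99L) {
    unloading_slope <- NA_real_
    degenerate <- TRUE
  } else {
    unloading_slope <- (v[100] - v[j80 + 1L]) / (99 - j80)
  }

  structure(list(
    fmean_stance = fmean_stance, fmean_load = fmean_load,
    fmean_mid = fmean_mid, fmean_unload = fmean_unload,
    fz2 = ext$fz2, fz3 = ext$fz3, fz4 = ext$fz4,
    loading_slope = loading_slope, unloading_slope = unloading_slope,
    i80 = i80, j80 = j80, degenerate = degenerate),
    class = "stance_parameters")
}

#' @export
print.stance_parameters <- function(x, ...) {
  cat("<stance_parameters>\n")
  cat(sprintf("  means  (%%BW): stance %.2f | load %.2f | mid %.2f | unload %.2f\n",
              x$fmean_stance, x$fmean_load, x$fmean_mid, x$fmean_unload))
  cat(sprintf("  extrema(%%BW): Fz2 %.2f | Fz3 %.2f | Fz4 %.2f\n",
              x$fz2, x$fz3, x$fz4))
  cat(sprintf("  slopes (%%BW/%%stance): loading %.4f | unloading %.4f%s\n",
              x$loading_slope, x$unloading_slope,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.stance_parameters <- function(x, ...) {
  data.frame(fmean_stance = x$fmean_stance, fmean_load = x$fmean_load,
             fmean_mid = x$fmean_mid, fmean_unload = x$fmean_unload,
             fz2 = x$fz2, fz3 = x$fz3, fz4 = x$fz4,
             loading_slope = x$loading_slope,
             unloading_slope = x$unloading_slope,
             degenerate = x$degenerate)
}
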