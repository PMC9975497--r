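#' Gaussian filter configuration
#'
#' Smoothing used only to locate extremum positions; parameter values are
#' read back from the unfiltered curve. The defaults (sigma 3, kernel
#' size 7) deliberately prioritize eliminating extremum ambiguity over
#' signal fidelity.
#'
#' @param sigma kernel standard deviation in index units.
#' @param kernel_size odd number of taps.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(sigma = 3, kernel_size = 7) {
  if (sigma <= 0) stop("sigma must be positive")
  if (kernel_size %% 2 != 1 || kernel_size < 1)
    stop("kernel_size must be a positive odd integer")
  structure(list(sigma = sigma, kernel_size = kernel_size),
            class = "filter_config")
}

#' Truncated Gaussian kernel weights
#' @param cfg a [filter_config].
#' @return numeric vector of length `kernel_size`, summing to 1.
#' @export
gaussian_kernel <- function(cfg = filter_config()) {
  h <- (cfg$kernel_size - 1) / 2
  k <- seq(-h, h)
  w <- exp(-k^2 / (2 * cfg$sigma^2))
  w / sum(w)
}

#' Smooth a normalized curve with a truncated Gaussian kernel
#'
#' Discrete convolution with the normalized kernel from
#' [gaussian_kernel()]; edges are handled by mirror reflection about the
#' boundary sample (the boundary value itself is not duplicated), so
#' constants are preserved exactly.
#'
#' @param curve numeric vector (typically the 100-point normalized curve).
#' @param cfg a [filter_config].
#' @return filtered curve, same length.
#' @export
gaussian_filter_curve <- function(curve, cfg = filter_config()) {
  if (inherits(curve, "normalized_stance")) curve <- curve$values
  n <- length(curve)
  h <- (cfg$kernel_size - 1) / 2
  if (h == 0) return(curve)
  if (n <= h) stop("curve shorter than kernel half-width")
  w <- gaussian_kernel(cfg)
  padded <- c(curve[(h + 1):2], curve, curve[(n - 1):(n - h)])
  # symmetric kernel: centered convolution as a sum of shifted slices
  out <- w[1] * padded[1:n]
  for (k in 2:length(w)) out <- out + w[k] * padded[k:(n + k - 1)]
  out
}

#' Find local extremum candidates on a filtered curve
#'
#' Scans for strict interior local maxima and minima. A plateau (run of
#' equal values) higher/lower than both neighbouring runs contributes a
#' single candidate at its center index (rounded down); runs touching
#' either end of the curve are not interior and yield no candidate.
#'
#' @param filtered numeric curve (filtered values).
#' @return data.frame with columns `index` (0-based), `polarity`
#'   (`"max"`/`"min"`), `filtered_value`; zero rows when the curve is
#'   monotone.
#' @export
find_candidates <- function(filtered) {
  n <- length(filtered)
  d <- diff(filtered)
  if (n >= 3 && !any(d == 0)) {
    # no plateaus: plain sign-change scan
    up <- d > 0
    rising <- up[-(n - 1)]
    next_up <- up[-1]
    mx <- which(rising & !next_up) + 1L   # 1-based interior positions
    mn <- which(!rising & next_up) + 1L
    pos <- c(mx, mn)
    pol <- rep(c("max", "min"), c(length(mx), length(mn)))
    o <- order(pos)
    return(.cand_df(as.integer(pos[o] - 1L), pol[o], filtered[pos[o]]))
  }
  r <- rle(filtered)
  m <- length(r$values)
  if (m < 3) return(.cand_df(integer(0), character(0), numeric(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  j <- 2:(m - 1)
  is_max <- v[j] > v[j - 1] & v[j] > v[j + 1]
  is_min <- v[j] < v[j - 1] & v[j] < v[j + 1]
  keep <- which(is_max | is_min)
  if (length(keep) == 0) return(.cand_df(integer(0), character(0), numeric(0)))
  jj <- j[keep]
  center <- floor((starts[jj] + ends[jj]) / 2)  # 1-based
  .cand_df(as.integer(center - 1L), ifelse(is_max[keep], "max", "min"), v[jj])
}

# minimal data.frame constructor (data.frame() is too slow for the
# per-event hot path)
.cand_df <- function(index, polarity, filtered_value) {
  structure(list(index = index, polarity = polarity,
                 filtered_value = filtered_value),
            class = "data.frame",
            row.names = if (length(index)) c(NA_integer_, -length(index))
                        else integer(0))
}

# exactly two maxima and one minimum strictly between them?
.is_resolved <- function(cand) {
  mx <- sort(cand$index[cand$polarity == "max"])
  mn <- cand$index[cand$polarity == "min"]
  length(mx) == 2 && length(mn) == 1 && mn > mx[1] && mn < mx[2]
}

# cluster same-polarity candidate indices by transitive closure with
# pairwise gap <= pool; keep best filtered value per cluster, ties to the
# earlier index
.pool_filter <- function(cand, pool = 5) {
  keep <- logical(nrow(cand))
  for (pol in c("max", "min")) {
    rows <- which(cand$polarity == pol)
    if (length(rows) == 0) next
    rows <- rows[order(cand$index[rows])]
    idx <- cand$index[rows]
    cluster <- cumsum(c(1, diff(idx) > pool))
    for (cl in unique(cluster)) {
      members <- rows[cluster == cl]
      fv <- cand$filtered_value[members]
      best <- if (pol == "max") members[which.max(fv)] else members[which.min(fv)]
      keep[best] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

# strict monotone run length (in indices, capped at `reach`) moving away
# from 0-based index i on each side; decreasing for maxima, increasing
# for minima
.monotony_sides <- function(filtered, i, pol, reach = 5) {
  p <- i + 1L  # 1-based
  n <- length(filtered)
  run <- function(step) {
    d <- 0L
    while (d < reach) {
      a <- p + step * d
      b <- p + step * (d + 1L)
      if (b < 1L || b > n) break
      ok <- if (pol == "max") filtered[b] < filtered[a] else filtered[b] > filtered[a]
      if (!ok) break
      d <- d + 1L
    }
    d
  }
  c(left = run(-1L), right = run(1L))
}

#' Disambiguate extremum candidates into Fz2, Fz3, Fz4
#'
#' Applies the detection strategies in order, each only while the
#' candidate set is still ambiguous (not exactly two maxima with one
#' minimum strictly between them):
#'
#' (a) time plausibility: drop candidates in the first or last 10 indices;
#' (b) max/min-pool filtering: among same-polarity candidates within a
#'     pool of five indices keep the one with the highest (maxima) or
#'     lowest (minima) filtered value;
#' (c) monotony check: keep only candidates around which the filtered
#'     curve is strictly monotone, decreasing for maxima / increasing for
#'     minima, on both sides over five indices;
#' (d) monotony grace: if (c) leaves fewer than two maxima or fewer than
#'     one minimum, reinstate its rejects in descending order of the
#'     monotony distance achieved on their weaker side (ties broken by
#'     larger deviation from the curve mean) until the target of two
#'     maxima and one minimum is reached.
#'
#' Any final state other than two maxima enclosing one minimum is a
#' non-step event.
#'
#' @param cand candidate data.frame from [find_candidates()].
#' @param filtered the filtered curve the candidates came from.
#' @return list with elements `i_fz2`, `i_fz3`, `i_fz4` (0-based indices)
#'   and `strategies_applied`, or a [stance_rejection()] whose rule names
#'   the failing stage.
#' @export
disambiguate <- function(cand, filtered) {
  applied <- character(0)
  finish <- function(cand) {
    mx <- sort(cand$index[cand$polarity == "max"])
    mn <- cand$index[cand$polarity == "min"]
    if (length(mx) != 2 || length(mn) != 1)
      return(stance_rejection("candidate_count",
                              sprintf("%d maxima, %d minima after cascade",
                                      length(mx), length(mn))))
    if (!(mn > mx[1] && mn < mx[2]))
      return(stance_rejection("ordering",
                              "minimum not strictly between the maxima"))
    if (filtered[mn + 1L] > filtered[mx[1] + 1L] ||
        filtered[mn + 1L] > filtered[mx[2] + 1L])
      return(stance_rejection("ordering",
                              "minimum above a maximum on the filtered curve"))
    list(i_fz2 = mx[1], i_fz3 = mn, i_fz4 = mx[2],
         strategies_applied = applied)
  }
  if (nrow(cand) == 0) return(stance_rejection("no_candidates"))
  if (.is_resolved(cand)) return(finish(cand))

  # (a) time plausibility
  applied <- c(applied, "time_plausibility")
  cand <- cand[cand$index >= 10 & cand$index < 90, , drop = FALSE]
  if (.is_resolved(cand)) return(finish(cand))

  # (b) pool filtering
  applied <- c(applied, "pool_filtering")
  cand <- .pool_filter(cand, pool = 5)
  if (.is_resolved(cand)) return(finish(cand))

  # (c) monotony check
  applied <- c(applied, "monotony_check")
  sides <- t(vapply(seq_len(nrow(cand)), function(r) {
    .monotony_sides(filtered, cand$index[r], cand$polarity[r], reach = 5)
  }, c(left = 0L, right = 0L)))
  passes <- sides[, "left"] == 5L & sides[, "right"] == 5L
  survivors <- cand[passes, , drop = FALSE]
  rejects <- cand[!passes, , drop = FALSE]
  if (nrow(rejects) > 0)
    rejects$monotony_distance <- pmin(sides[!passes, "left"],
                                      sides[!passes, "right"])
  if (.is_resolved(survivors)) return(finish(survivors))

  # (d) monotony grace
  applied <- c(applied, "monotony_grace")
  need <- c(max = 2L, min = 1L)
  cmean <- mean(filtered)
  for (pol in c("max", "min")) {
    have <- sum(survivors$polarity == pol)
    if (have >= need[[pol]]) next
    pool <- rejects[rejects$polarity == pol, , drop = FALSE]
    if (nrow(pool) == 0) next
    ord <- order(-pool$monotony_distance, -abs(pool$filtered_value - cmean))
    take <- pool[ord, , drop = FALSE][seq_len(min(need[[pol]] - have, nrow(pool))),
                                      c("index", "polarity", "filtered_value"),
                                      drop = FALSE]
    survivors <- rbind(survivors[, c("index", "polarity", "filtered_value"),
                                 drop = FALSE], take)
  }
  finish(survivors)
}

#' Locate Fz2, Fz3, Fz4 on a normalized stance curve
#'
#' Runs the full extremum pipeline: Gaussian smoothing (position finding
#' only), candidate scan, and the disambiguation cascade. The force
#' values reported are read from the unfiltered normalized curve at the
#' selected indices, preserving high-frequency detail the filter would
#' flatten.
#'
#' @param ns a `normalized_stance` (or bare 100-point numeric curve).
#' @param cfg a [filter_config].
#' @return object of class `stance_extrema` (fields `i_fz2`, `i_fz3`,
#'   `i_fz4` as 0-based indices and `fz2`, `fz3`, `fz4` in % BW), or a
#'   [stance_rejection()].
#' @export
locate_extrema <- function(ns, cfg = filter_config()) {
  values <- if (inherits(ns, "normalized_stance")) ns$values else as.numeric(ns)
  if (length(values) != 100)
    stop("locate_extrema expects a 100-point normalized curve")
  filtered <- gaussian_filter_curve(values, cfg)
  cand <- find_candidates(filtered)
  res <- disambiguate(cand, filtered)
  if (is_rejection(res)) return(res)
  structure(list(
    i_fz2 = res$i_fz2, i_fz3 = res$i_fz3, i_fz4 = res$i_fz4,
    fz2 = values[res$i_fz2 + 1L], fz3 = values[res$i_fz3 + 1L],
    fz4 = values[res$i_fz4 + 1L],
    strategies_applied = res$strategies_applied),
    class = "stance_extrema")
}

#' @export
print.stance_extrema <- function(x, ...) {
  cat(sprintf("<stance_extrema> Fz2 %.2f%%BW @%d | Fz3 %.2f%%BW @%d | Fz4 %.2f%%BW @%d\n",
              x$fz2, x$i_fz2, x$fz3, x$i_fz3, x$fz4, x$i_fz4))
  if (length(x$strategies_applied))
    cat("  strategies:", paste(x$strategies_applied, collapse = " -> "), "\n")
  invisible(x)
}
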