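# Independent reference implementations used to cross-check the package.
# They are written as plain per-window / per-index scans, deliberately
# sharing no code or algorithmic structure with the package internals.

# --- segmentation oracle -------------------------------------------------
# Enumerates, for every possible left edge, the largest qualifying window
# by walking right one sample at a time. A window qualifies when it
# starts and ends on a non-missing sample strictly above the threshold,
# contains no non-missing sample at or below it, and no run of more than
# max_gap consecutive missing samples. Left edges that could be absorbed
# into a longer qualifying window to the left are skipped (maximality),
# and the inclusive duration gate is applied last.
oracle_segment <- function(force, timestamps, cfg) {
  n <- length(force)
  above <- function(i) !is.na(force[i]) && force[i] > cfg$force_threshold
  below <- function(i) !is.na(force[i]) && force[i] <= cfg$force_threshold

  left_extendable <- function(i) {
    g <- 0
    k <- i - 1
    while (k >= 1 && is.na(force[k]) && g < cfg$max_gap) {
      g <- g + 1
      k <- k - 1
    }
    k >= 1 && above(k)
  }

  out <- list()
  for (i in seq_len(n)) {
    if (!above(i) || left_extendable(i)) next
    jmax <- i
    gap <- 0
    j <- i + 1
    while (j <= n) {
      if (below(j)) break
      if (is.na(force[j])) {
        gap <- gap + 1
        if (gap > cfg$max_gap) break
      } else {
        gap <- 0
        jmax <- j
      }
      j <- j + 1
    }
    dur <- timestamps[jmax] - timestamps[i]
    if (dur >= cfg$min_duration && dur <= cfg$max_duration)
      out[[length(out) + 1]] <- c(start = i, end = jmax)
  }
  out
}

# --- extremum pipeline oracle --------------------------------------------
# Filter, candidate scan and rule cascade re-coded as literal per-index
# loops. Returns list(i_fz2, i_fz3, i_fz4) (0-based) or NULL (non-step).
oracle_extrema <- function(curve, sigma = 3, kernel_size = 7) {
  n <- length(curve)
  h <- (kernel_size - 1) / 2
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w <- w / sum(w)
  mirror <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  fc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(kernel_size))
      acc <- acc + w[k] * curve[mirror(i + k - 1 - h)]
    fc[i] <- acc
  }

  # candidates: strict interior extrema, plateaus -> floor of center
  cand <- list()
  i <- 2
  while (i <= n - 1) {
    j <- i
    while (j < n && fc[j + 1] == fc[i]) j <- j + 1
    if (j <= n - 1 && i >= 2) {
      l <- fc[i - 1]; rgt <- fc[j + 1]
      ctr <- floor((i + j) / 2)
      if (fc[i] > l && fc[i] > rgt)
        cand[[length(cand) + 1]] <- list(idx = ctr - 1, pol = "max")
      else if (fc[i] < l && fc[i] < rgt)
        cand[[length(cand) + 1]] <- list(idx = ctr - 1, pol = "min")
    }
    i <- j + 1
  }

  get <- function(cands, pol) sort(vapply(
    Filter(function(c) c$pol == pol, cands), function(c) c$idx, numeric(1)))
  solved <- function(cands) {
    mx <- get(cands, "max"); mn <- get(cands, "min")
    length(mx) == 2 && length(mn) == 1 && mn > mx[1] && mn < mx[2]
  }
  result <- function(cands) {
    if (!solved(cands)) return(NULL)
    mx <- get(cands, "max"); mn <- get(cands, "min")
    # the minimum must not exceed either maximum on the filtered curve
    if (fc[mn + 1] > fc[mx[1] + 1] || fc[mn + 1] > fc[mx[2] + 1]) return(NULL)
    list(i_fz2 = mx[1], i_fz3 = mn, i_fz4 = mx[2])
  }
  if (length(cand) == 0) return(NULL)
  if (solved(cand)) return(result(cand))

  # (a) first/last 10 indices
  cand <- Filter(function(c) c$idx >= 10 && c$idx < 90, cand)
  if (solved(cand)) return(result(cand))

  # (b) pool filtering: connected components of same-polarity candidates
  # linked when within 5 indices; keep the strongest of each component,
  # ties to the earlier index
  pooled <- list()
  for (pol in c("max", "min")) {
    members <- Filter(function(c) c$pol == pol, cand)
    used <- rep(FALSE, length(members))
    for (s in seq_along(members)) {
      if (used[s]) next
      comp <- s
      used[s] <- TRUE
      grew <- TRUE
      while (grew) {
        grew <- FALSE
        for (t in seq_along(members)) {
          if (used[t]) next
          near <- any(vapply(comp, function(c0)
            abs(members[[t]]$idx - members[[c0]]$idx) <= 5, logical(1)))
          if (near) {
            comp <- c(comp, t)
            used[t] <- TRUE
            grew <- TRUE
          }
        }
      }
      vals <- vapply(comp, function(c0) fc[members[[c0]]$idx + 1], numeric(1))
      idxs <- vapply(comp, function(c0) members[[c0]]$idx, numeric(1))
      target <- if (pol == "max") max(vals) else min(vals)
      hit <- comp[vals == target]
      best <- hit[which.min(idxs[vals == target])]
      pooled[[length(pooled) + 1]] <- members[[best]]
    }
  }
  cand <- pooled[order(vapply(pooled, function(c) c$idx, numeric(1)))]
  if (solved(cand)) return(result(cand))

  # (c) monotony check over 5 indices each side
  mono_len <- function(idx, pol, dir) {
    p <- idx + 1
    d <- 0
    while (d < 5) {
      a <- p + dir * d; b <- p + dir * (d + 1)
      if (b < 1 || b > n) break
      if (pol == "max" && !(fc[b] < fc[a])) break
      if (pol == "min" && !(fc[b] > fc[a])) break
      d <- d + 1
    }
    d
  }
  keep <- vapply(cand, function(c)
    mono_len(c$idx, c$pol, -1) == 5 && mono_len(c$idx, c$pol, 1) == 5,
    logical(1))
  surv <- cand[keep]
  elim <- cand[!keep]
  if (solved(surv)) return(result(surv))

  # (d) monotony grace
  cm <- mean(fc)
  for (pol in c("max", "min")) {
    want <- if (pol == "max") 2 else 1
    while (sum(vapply(surv, function(c) c$pol == pol, logical(1))) < want) {
      pool <- which(vapply(elim, function(c) c$pol == pol, logical(1)))
      if (length(pool) == 0) break
      score <- vapply(pool, function(p) {
        c0 <- elim[[p]]
        min(mono_len(c0$idx, c0$pol, -1), mono_len(c0$idx, c0$pol, 1))
      }, numeric(1))
      tie <- vapply(pool, function(p)
        abs(fc[elim[[p]]$idx + 1] - cm), numeric(1))
      best <- pool[order(-score, -tie)][1]
      surv[[length(surv) + 1]] <- elim[[best]]
      elim <- elim[-best]
    }
  }
  result(surv)
}

# --- OLS by normal equations ---------------------------------------------
# Closed-form multiple regression: coefficients, standardized betas,
# t-test p-values, R^2 / adjusted R^2 and overall F p-value.
ols_normal_equations <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X) - 1  # X includes the intercept column
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta[, 1] / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p - 1)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- ((tss - rss) / p) / sigma2
  fp <- stats::pf(fstat, p, n - p - 1, lower.tail = FALSE)
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  list(coef = beta[, 1], se = se, p = pval,
       beta_std = beta[-1, 1] * sds / stats::sd(y),
       r2 = r2, adj_r2 = adj, f_p = fp)
}
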