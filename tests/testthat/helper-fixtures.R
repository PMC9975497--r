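# Curve and recording fixtures built in code.

# M-shaped curve over indices 0..99 with extrema exactly at the given
# 0-based indices, built from raised-cosine ease segments (zero slope at
# every extremum, strictly monotone between).
index_m_curve <- function(i2 = 25, i3 = 50, i4 = 75,
                          fz2 = 110, fz3 = 75, fz4 = 105,
                          f0 = 0, f99 = 0) {
  h <- function(x) 0.5 * (1 - cos(pi * x))
  i <- 0:99
  v <- numeric(100)
  s <- i <= i2
  v[s] <- f0 + (fz2 - f0) * h(i[s] / i2)
  s <- i > i2 & i <= i3
  v[s] <- fz3 + (fz2 - fz3) * (1 - h((i[s] - i2) / (i3 - i2)))
  s <- i > i3 & i <= i4
  v[s] <- fz3 + (fz4 - fz3) * h((i[s] - i3) / (i4 - i3))
  s <- i > i4
  v[s] <- f99 + (fz4 - f99) * (1 - h((i[s] - i4) / (99 - i4)))
  v
}

# piecewise-linear M-curve (fractions of body weight): rise 0 -> 1 over
# indices 0-20, down to 0.8 at 50, up to 1.0 at 80, down to 0 at 99
piecewise_linear_m <- function() {
  i <- 0:99
  v <- numeric(100)
  s <- i <= 20;           v[s] <- i[s] / 20
  s <- i > 20 & i <= 50;  v[s] <- 1 - 0.2 * (i[s] - 20) / 30
  s <- i > 50 & i <= 80;  v[s] <- 0.8 + 0.2 * (i[s] - 50) / 30
  s <- i > 80;            v[s] <- 1 - (i[s] - 80) / 19
  v
}

# stance_extrema constructed directly (for parameter tests)
make_extrema <- function(curve, i2, i3, i4) {
  structure(list(i_fz2 = i2, i_fz3 = i3, i_fz4 = i4,
                 fz2 = curve[i2 + 1], fz3 = curve[i3 + 1],
                 fz4 = curve[i4 + 1], strategies_applied = character(0)),
            class = "stance_extrema")
}

make_normalized <- function(values, subject_id = "T1", side = "left",
                            duration = 650) {
  structure(list(subject_id = subject_id, side = side, values = values,
                 source_duration = duration),
            class = "normalized_stance")
}

make_recording <- function(force, subject_id = "T1", side = "left",
                           rate = 100) {
  insole_recording(subject_id, side, (seq_along(force) - 1) * 1000 / rate,
                   force, rate)
}

# random force sequence for segmentation oracle equivalence: mixes block
# structure, missing runs and noise so all rule branches are exercised
random_force_sequence <- function(n) {
  style <- sample(1:3, 1)
  if (style == 1) {
    f <- pmax(0, cumsum(stats::rnorm(n, 0, 25)) + stats::runif(1, -50, 150))
  } else if (style == 2) {
    f <- numeric(n)
    pos <- 1
    while (pos < n) {
      len <- sample(5:60, 1)
      lvl <- sample(c(0, 10, 200, 500), 1)
      f[pos:min(n, pos + len - 1)] <- lvl
      pos <- pos + len
    }
  } else {
    f <- stats::runif(n, 0, 60)
  }
  # sprinkle missing runs of length 1-5
  k <- sample(0:4, 1)
  for (z in seq_len(k)) {
    start <- sample(seq_len(n), 1)
    len <- sample(1:5, 1)
    f[start:min(n, start + len - 1)] <- NA
  }
  f
}

# random smooth stance-like curve for extremum-cascade equivalence:
# an M-curve base plus optional extra bumps, low-frequency warp and mild
# jitter; some draws are monotone or multi-peaked on purpose
random_smooth_curve <- function() {
  kind <- sample(1:4, 1, prob = c(0.55, 0.2, 0.15, 0.1))
  i <- 0:99
  if (kind == 4) { # monotone / flat-ish, should be rejected
    return(cumsum(stats::runif(100, 0, 0.5)))
  }
  i2 <- sample(12:40, 1)
  i3 <- sample((i2 + 5):65, 1)
  i4 <- sample((i3 + 5):92, 1)
  v <- index_m_curve(i2, i3, i4,
                     fz2 = stats::runif(1, 95, 125),
                     fz3 = stats::runif(1, 55, 90),
                     fz4 = stats::runif(1, 90, 120),
                     f0 = stats::runif(1, 0, 10),
                     f99 = stats::runif(1, 0, 10))
  if (kind >= 2) { # add 1-2 extra bumps to create ambiguity
    for (b in seq_len(sample(1:2, 1))) {
      ctr <- sample(5:95, 1)
      wid <- sample(3:12, 1)
      amp <- stats::runif(1, -12, 12)
      x <- (i - ctr) / wid
      bump <- ifelse(abs(x) <= 1, 0.5 * (1 + cos(pi * x)), 0)
      v <- v + amp * bump
    }
  }
  if (kind == 3) { # low-frequency warp
    v <- v + stats::runif(1, -6, 6) * sin(2 * pi * i / stats::runif(1, 40, 120))
  }
  v + stats::rnorm(100, 0, 0.2)
}

# mean of a truncated normal (closed form), for cohort-moment checks
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
}
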