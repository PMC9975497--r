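# truncated-normal sampler (rejection from the untruncated normal; all
# use cases here truncate well inside +/- 6 SD so acceptance is high)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (upper < mean - 6 * sd || lower > mean + 6 * sd)
    stop("infeasible truncation: range excludes mean +/- 6 SD")
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    x <- stats::rnorm(n - filled, mean, sd)
    x <- x[x >= lower & x <= upper]
    if (length(x) > 0) {
      out[filled + seq_along(x)] <- x
      filled <- filled + length(x)
    }
  }
  out
}

#' Specification of a synthetic walking cohort
#'
#' Describes the population the generator draws from: truncated-normal
#' anthropometric distributions (defaults reproduce the published
#' characteristics of a healthy adult treadmill cohort: age 43.65 +/-
#' 17.59 years in 18-87, height 173.70 +/- 11.22 cm in 157-203, weight
#' 79.81 +/- 27.85 kg in 43.9-170.8, grip 35.41 +/- 12.46 kg in
#' 19.6-68.7), and the linear anthropometric effects planted on the three
#' force extrema of the stance curve. The default planted coefficients
#' are the published non-standardized regression coefficients for Fz2,
#' Fz3 and Fz4 (% BW per predictor unit), with exact zeros where no
#' effect was reported, so "no effect" is itself testable:
#' Fz2 ~ -0.008 x weight; Fz3 ~ -0.006 x weight + 0.012 x grip;
#' Fz4 ~ -0.010 x weight + 0.019 x grip.
#'
#' Residual subject-level SDs for the extremum targets are derived in
#' closed form from the planted effects and the predictor SDs so the
#' population R-squared matches `target_r2` (defaults: the published
#' adjusted R-squared of the three extrema: 0.376, 0.199, 0.282).
#'
#' @param n_subjects cohort size.
#' @param seed integer seed; all generator randomness flows from it.
#' @param age,height,weight,grip lists `(mean, sd, lower, upper)`.
#' @param planted 3 x 4 numeric matrix of raw coefficients, rows
#'   `fz2`,`fz3`,`fz4`, columns `age`,`height`,`weight`,`grip`.
#' @param target_r2 length-3 numeric, population R-squared targets used
#'   to calibrate the residual SDs of the three extremum targets.
#' @param baselines extremum targets (% BW) of the average subject.
#' @param stance_mean,stance_sd,stance_range stance duration distribution
#'   (ms), truncated normal.
#' @param swing_mean,swing_sd,swing_range swing duration distribution (ms).
#' @param peak_timing fractions of stance duration at which Fz2, Fz3 and
#'   Fz4 occur.
#' @param noise_sd additive sensor noise SD in Newton.
#' @param missing_prob per-sample probability of a lost (missing) sample.
#' @param resid_sd optional explicit residual SDs (length 3 or scalar,
#'   % BW) overriding the `target_r2` calibration; 0 plants the effects
#'   noise-free.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 37, seed = 1,
                        age = list(mean = 43.65, sd = 17.59, lower = 18, upper = 87),
                        height = list(mean = 173.70, sd = 11.22, lower = 157, upper = 203),
                        weight = list(mean = 79.81, sd = 27.85, lower = 43.9, upper = 170.8),
                        grip = list(mean = 35.41, sd = 12.46, lower = 19.6, upper = 68.7),
                        planted = default_planted_effects(),
                        target_r2 = c(fz2 = 0.376, fz3 = 0.199, fz4 = 0.282),
                        baselines = c(fz2 = 110, fz3 = 75, fz4 = 105),
                        stance_mean = 650, stance_sd = 40,
                        stance_range = c(450, 900),
                        swing_mean = 400, swing_sd = 30,
                        swing_range = c(300, 500),
                        peak_timing = c(fz2 = 0.28, fz3 = 0.50, fz4 = 0.72),
                        noise_sd = 3, missing_prob = 0.004,
                        resid_sd = NULL) {
  if (n_subjects < 0) stop("n_subjects must be >= 0")
  dists <- list(age = age, height = height, weight = weight, grip = grip)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (d$sd <= 0) stop(nm, ": sd must be positive")
    if (d$lower > d$mean || d$upper < d$mean)
      stop(nm, ": range must contain the mean")
  }
  stopifnot(is.matrix(planted), nrow(planted) == 3, ncol(planted) == 4,
            identical(rownames(planted), c("fz2", "fz3", "fz4")),
            identical(colnames(planted), c("age", "height", "weight", "grip")))
  if (is.null(resid_sd)) {
    pred_sd <- vapply(dists, function(d) d$sd, numeric(1))
    signal_var <- as.numeric((planted^2) %*% pred_sd^2)
    resid_sd <- sqrt(signal_var * (1 - target_r2) / target_r2)
    # extrema with no planted effect would get zero residual SD; floor at
    # a small positive spread so the cohort is never degenerate
    resid_sd[!is.finite(resid_sd) | resid_sd == 0] <- 0.25
  } else {
    resid_sd <- rep_len(as.numeric(resid_sd), 3)
  }
  names(resid_sd) <- c("fz2", "fz3", "fz4")
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    age = age, height = height, weight = weight, grip = grip,
    planted = planted, target_r2 = target_r2, resid_sd = resid_sd,
    baselines = baselines,
    stance_mean = stance_mean, stance_sd = stance_sd,
    stance_range = stance_range,
    swing_mean = swing_mean, swing_sd = swing_sd, swing_range = swing_range,
    peak_timing = peak_timing,
    noise_sd = noise_sd, missing_prob = missing_prob),
    class = "cohort_spec")
}

#' Default planted anthropometric effects on the force extrema
#'
#' @return 3 x 4 matrix (rows fz2, fz3, fz4; columns age, height, weight,
#'   grip) of raw coefficients in % BW per predictor unit.
#' @export
default_planted_effects <- function() {
  m <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(c("fz2", "fz3", "fz4"),
                              c("age", "height", "weight", "grip")))
  m["fz2", "weight"] <- -0.008
  m["fz3", "weight"] <- -0.006
  m["fz3", "grip"] <- 0.012
  m["fz4", "weight"] <- -0.010
  m["fz4", "grip"] <- 0.019
  m
}

#' Draw a synthetic cohort of subject profiles
#'
#' Truncated-normal sampling of age, height, weight and grip; BMI derived
#' from height and weight; sex assigned at random (cosmetic only, no
#' planted sex effect).
#'
#' @param spec a [cohort_spec].
#' @param seed seed to apply before sampling; `NULL` continues the
#'   current RNG stream (used internally by [simulate_cohort()]).
#' @return subject profile data.frame.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  draw <- function(d) rtrunc_norm(n, d$mean, d$sd, d$lower, d$upper)
  df <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = draw(spec$age), height = draw(spec$height),
    weight = draw(spec$weight), grip = draw(spec$grip),
    stringsAsFactors = FALSE)
  df$bmi <- df$weight / (df$height / 100)^2
  df$sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  if (n == 0) df <- df[0, , drop = FALSE]
  df
}

#' Derive a subject's gait-curve shape targets
#'
#' Each extremum target is baseline + sum(planted coefficient x centered
#' predictor) + Normal(0, residual SD); predictors are centered at the
#' spec's population means so the average subject hits the baselines.
#' Target sets violating Fz3 < min(Fz2, Fz4) are redrawn up to 10 times.
#'
#' @param profile one-row subject profile.
#' @param spec a [cohort_spec].
#' @param seed optional seed for the target noise; `NULL` continues the
#'   current RNG stream.
#' @return list of class `gait_shape`: `fz2_target`, `fz3_target`,
#'   `fz4_target` (% BW) plus the timing/noise constants from the spec.
#' @export
shape_from_profile <- function(profile, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  centered <- c(age = profile$age - spec$age$mean,
                height = profile$height - spec$height$mean,
                weight = profile$weight - spec$weight$mean,
                grip = profile$grip - spec$grip$mean)
  det <- spec$baselines + as.numeric(spec$planted %*% centered)
  for (attempt in 1:10) {
    targets <- det + stats::rnorm(3, 0, spec$resid_sd)
    if (targets[2] < min(targets[1], targets[3])) break
    if (attempt == 10)
      stop("could not draw targets with Fz3 below both maxima for subject ",
           profile$subject_id)
  }
  structure(list(
    subject_id = profile$subject_id,
    fz2_target = unname(targets[1]), fz3_target = unname(targets[2]),
    fz4_target = unname(targets[3]),
    peak_timing = spec$peak_timing,
    stance_mean = spec$stance_mean, stance_sd = spec$stance_sd,
    stance_range = spec$stance_range,
    swing_mean = spec$swing_mean, swing_sd = spec$swing_sd,
    swing_range = spec$swing_range,
    noise_sd = spec$noise_sd, missing_prob = spec$missing_prob),
    class = "gait_shape")
}

#' Closed-form stance template
#'
#' Smooth M-shaped curve built from four raised-cosine ease segments
#' joined with zero slope at the three extrema and at both ends, so the
#' extrema sit exactly at the requested fractions of stance duration with
#' exactly the requested values, and the curve is strictly monotone
#' between them.
#'
#' @param u fraction of stance duration in `[0, 1]`.
#' @param fz2,fz3,fz4 extremum values (% BW).
#' @param timing length-3 fractions at which the extrema occur.
#' @return force in % BW at `u`.
#' @export
stance_template <- function(u, fz2, fz3, fz4,
                            timing = c(fz2 = 0.28, fz3 = 0.50, fz4 = 0.72)) {
  c2 <- timing[[1]]; c3 <- timing[[2]]; c4 <- timing[[3]]
  h <- function(x) 0.5 * (1 - cos(pi * x))
  out <- numeric(length(u))
  s1 <- u <= c2
  s2 <- u > c2 & u <= c3
  s3 <- u > c3 & u <= c4
  s4 <- u > c4
  out[s1] <- fz2 * h(u[s1] / c2)
  out[s2] <- fz3 + (fz2 - fz3) * (1 - h((u[s2] - c2) / (c3 - c2)))
  out[s3] <- fz3 + (fz4 - fz3) * h((u[s3] - c3) / (c4 - c3))
  out[s4] <- fz4 * (1 - h((u[s4] - c4) / (1 - c4)))
  out
}

#' Synthesize one subject's pair of insole recordings
#'
#' Renders alternating stance/swing cycles over the recording duration at
#' the nominal sample rate. Each stance is the closed-form
#' [stance_template()] hitting the subject's extremum targets, converted
#' from % body weight to Newton via the subject's weight; additive
#' Gaussian sensor noise (floored at 0 N) and Bernoulli missing samples
#' are applied to the whole series. The right foot is phase-shifted by
#' half a gait cycle.
#'
#' @param profile one-row subject profile (needs `weight`).
#' @param shapes a `gait_shape` from [shape_from_profile()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param duration_s recording length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param g gravitational acceleration (m/s^2).
#' @return list with elements `left` and `right`, each an
#'   [insole_recording].
#' @export
synthesize_recording <- function(profile, shapes, seed = NULL,
                                 duration_s = 60, sample_rate = 100,
                                 g = 9.81) {
  stopifnot(inherits(shapes, "gait_shape"))
  if (!is.null(seed)) set.seed(seed)
  n <- duration_s * sample_rate
  ts <- (seq_len(n) - 1) * (1000 / sample_rate)
  newton <- profile$weight * g / 100  # N per % BW

  render_side <- function(t_offset) {
    f <- numeric(n)
    t <- t_offset
    total_ms <- duration_s * 1000
    while (t < total_ms) {
      d <- rtrunc_norm(1, shapes$stance_mean, shapes$stance_sd,
                       shapes$stance_range[1], shapes$stance_range[2])
      sw <- rtrunc_norm(1, shapes$swing_mean, shapes$swing_sd,
                        shapes$swing_range[1], shapes$swing_range[2])
      i0 <- ceiling(t * sample_rate / 1000) + 1
      i1 <- floor((t + d) * sample_rate / 1000) + 1
      if (i0 >= 1 && i0 <= min(i1, n)) {
        idx <- i0:min(i1, n)
        u <- (ts[idx] - t) / d
        f[idx] <- stance_template(u, shapes$fz2_target, shapes$fz3_target,
                                  shapes$fz4_target, shapes$peak_timing) *
          newton
      }
      t <- t + d + sw
    }
    if (shapes$noise_sd > 0)
      f <- pmax(0, f + stats::rnorm(n, 0, shapes$noise_sd))
    if (shapes$missing_prob > 0)
      f[stats::runif(n) < shapes$missing_prob] <- NA_real_
    f
  }

  half_cycle <- (shapes$stance_mean + shapes$swing_mean) / 2
  list(
    left = insole_recording(profile$subject_id, "left", ts,
                            render_side(0), sample_rate),
    right = insole_recording(profile$subject_id, "right", ts,
                             render_side(half_cycle), sample_rate))
}

#' Simulate a complete synthetic study
#'
#' Draws a cohort, derives per-subject curve-shape targets, and renders a
#' pair of 1-minute insole recordings per subject. All randomness flows
#' from `spec$seed` through a single RNG stream, so identical specs give
#' identical output.
#'
#' @param spec a [cohort_spec].
#' @param duration_s recording length per subject in seconds.
#' @return list of class `cohort_sim`: `subjects` (profile data.frame),
#'   `recordings` (named list; per subject a list with `left`/`right`),
#'   `shapes` (per-subject targets), `spec`.
#' @export
simulate_cohort <- function(spec, duration_s = 60) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subjects <- sample_cohort(spec, seed = NULL)
  shapes <- list()
  recordings <- list()
  for (i in seq_len(nrow(subjects))) {
    pr <- subjects[i, ]
    sh <- shape_from_profile(pr, spec, seed = NULL)
    shapes[[pr$subject_id]] <- sh
    recordings[[pr$subject_id]] <-
      synthesize_recording(pr, sh, seed = NULL, duration_s = duration_s)
  }
  structure(list(subjects = subjects, recordings = recordings,
                 shapes = shapes, spec = spec),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects, %d recordings (seed %d)\n",
              nrow(x$subjects), 2 * length(x$recordings), x$spec$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One CSV per recording (`<subject>_<side>.csv` with columns
#' `time,force`; missing samples as empty cells), a `subjects.csv`, and a
#' `ground_truth.json` with the planted coefficients and per-subject
#' shape targets.
#'
#' @param sim a `cohort_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (sid in names(sim$recordings)) {
    for (side in c("left", "right")) {
      rec <- sim$recordings[[sid]][[side]]
      path <- file.path(dir, sprintf("%s_%s.csv", sid, side))
      lines <- c("time,force",
                 paste(rec$timestamps,
                       ifelse(is.na(rec$force), "",
                              sprintf("%.9g", rec$force)),
                       sep = ","))
      con <- file(path, open = "wb")
      writeLines(lines, con)
      close(con)
    }
  }
  gt <- list(
    seed = sim$spec$seed,
    planted = as.data.frame(sim$spec$planted),
    baselines = as.list(sim$spec$baselines),
    resid_sd = as.list(sim$spec$resid_sd),
    targets = lapply(sim$shapes, function(s)
      list(fz2 = s$fz2_target, fz3 = s$fz3_target, fz4 = s$fz4_target)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
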