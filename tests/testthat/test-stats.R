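make_agg <- function(sid, curve, pm = NULL) {
  if (is.null(pm))
    pm <- stats::setNames(rep(1, 9), stancecurve:::PARAM_COLUMNS)
  structure(list(subject_id = sid, mean_curve = curve,
                 n_steps_accepted = 5L, n_events_rejected = 0L,
                 parameter_means = pm),
            class = "subject_aggregate")
}

test_that("subject aggregation averages curves index-wise and pools parameters", {
  v <- index_m_curve()
  curves <- list(make_normalized(v), make_normalized(v), make_normalized(v))
  ext <- locate_extrema(v)
  p <- compute_parameters(v, ext)
  p1 <- p; p1$fz2 <- 0.5
  p2 <- p; p2$fz2 <- 1.5
  agg <- aggregate_subject(curves, list(p, p1, p2))
  expect_equal(agg$mean_curve, v)
  expect_equal(unname(agg$parameter_means["fz2"]),
               mean(c(p$fz2, 0.5, 1.5)))
  expect_equal(agg$n_steps_accepted, 3)
})

test_that("subjects with only rejected events are excluded with a warning", {
  v <- index_m_curve()
  p <- compute_parameters(v, locate_extrema(v))
  p$degenerate <- TRUE
  expect_warning(res <- aggregate_subject(list(make_normalized(v)), list(p)),
                 "no accepted")
  expect_null(res)
})

test_that("group bands: identical members give a zero-width band", {
  v <- index_m_curve()
  aggs <- list(make_agg("a", v), make_agg("b", v),
               make_agg("c", v + 1), make_agg("d", v + 1))
  b <- group_curve_band(aggs, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(b$A$lower, b$A$upper)
  expect_equal(b$A$mean, v)
  expect_equal(b$B$mean, v + 1)
})

test_that("the 95% band halfwidth matches the closed-form t quantile at n = 2", {
  v0 <- rep(0, 100); v2 <- rep(2, 100)
  aggs <- list(make_agg("a", v0), make_agg("b", v2),
               make_agg("c", v0), make_agg("d", v0))
  b <- group_curve_band(aggs, c(TRUE, TRUE, FALSE, FALSE))
  # mean 1, sd sqrt(2), halfwidth t(.975, 1) * sqrt(2)/sqrt(2) = 12.7062
  expect_equal(b$A$mean, rep(1, 100))
  expect_equal(b$A$upper - b$A$mean, rep(12.7062047, 100), tolerance = 1e-6)
})

test_that("a singleton group is flagged with an undefined band", {
  aggs <- list(make_agg("a", rep(1, 100)), make_agg("b", rep(2, 100)),
               make_agg("c", rep(3, 100)))
  b <- group_curve_band(aggs, c(TRUE, FALSE, FALSE))
  expect_false(b$A$ci_defined)
  expect_true(all(is.na(b$A$lower)))
})

test_that("an exactly linear dependency is recovered perfectly", {
  set.seed(91)
  d <- data.frame(age = stats::rnorm(30, 45, 15),
                  height = stats::rnorm(30, 172, 10),
                  weight = stats::rnorm(30, 80, 20),
                  grip = stats::rnorm(30, 35, 10))
  d$bmi <- d$weight / (d$height / 100)^2
  d$fz2 <- 2 * d$weight + 5
  # lm warns about the zero-residual fit; exactness is the point here
  f <- suppressWarnings(fit_model(d, "fz2", "main"))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "weight"], 2,
               tolerance = 1e-9)
  expect_equal(f$intercept, 5, tolerance = 1e-7)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)
})

test_that("standardized beta equals the Pearson correlation for a lone predictor", {
  set.seed(92)
  n <- 60
  x <- stats::rnorm(n)
  y <- 1.5 * x + stats::rnorm(n, 0, 0.7)
  # build the other predictors exactly orthogonal to (1, x, y)
  orth <- function(z) stats::residuals(stats::lm(z ~ x + y))
  d <- data.frame(age = 45 + orth(stats::rnorm(n)),
                  height = 172 + orth(stats::rnorm(n)),
                  grip = 35 + orth(stats::rnorm(n)),
                  weight = 80 + 10 * x)
  d$bmi <- d$weight / (d$height / 100)^2
  d$fz3 <- y
  f <- fit_model(d, "fz3", "main")
  beta_w <- f$coefficients$beta[f$coefficients$term == "weight"]
  expect_equal(beta_w, stats::cor(d$weight, y), tolerance = 1e-8)
})

test_that("OLS agrees with the normal equations on random designs", {
  set.seed(93)
  for (r in 1:5) {
    n <- 30
    d <- data.frame(age = stats::rnorm(n, 45, 15),
                    height = stats::rnorm(n, 172, 10),
                    weight = stats::rnorm(n, 80, 20),
                    grip = stats::rnorm(n, 35, 10))
    d$bmi <- d$weight / (d$height / 100)^2
    d$fz4 <- 100 - 0.01 * d$weight + 0.02 * d$grip + stats::rnorm(n, 0, 0.5)
    f <- fit_model(d, "fz4", "main")
    X <- cbind(1, as.matrix(d[, c("age", "height", "weight", "grip")]))
    o <- ols_normal_equations(X, d$fz4)
    expect_equal(f$coefficients$estimate, unname(o$coef[-1]), tolerance = 1e-8)
    expect_equal(f$coefficients$beta, unname(o$beta_std), tolerance = 1e-8)
    expect_equal(f$coefficients$p, unname(o$p[-1]), tolerance = 1e-8)
    expect_equal(f$adjusted_r2, o$adj_r2, tolerance = 1e-10)
    expect_equal(f$model_p, o$f_p, tolerance = 1e-10)
    expect_lt(f$adjusted_r2, f$r2)
  }
})

test_that("rank-deficient designs raise a collinearity error naming the term", {
  set.seed(94)
  d <- data.frame(age = stats::rnorm(10, 45, 15),
                  height = stats::rnorm(10, 172, 10))
  d$weight <- stats::rnorm(10, 80, 20)
  d$grip <- 2 * d$age + 3 * d$height  # exact linear combination
  d$bmi <- d$weight / (d$height / 100)^2
  d$fz2 <- stats::rnorm(10, 110, 1)
  expect_error(fit_model(d, "fz2", "main"), "collinear.*grip")
})

test_that("fit_all produces 18 fits and masks non-significant cells", {
  set.seed(95)
  n <- 40
  d <- data.frame(subject_id = sprintf("S%02d", 1:n),
                  age = stats::rnorm(n, 45, 15),
                  height = stats::rnorm(n, 172, 10),
                  weight = stats::rnorm(n, 80, 20),
                  grip = stats::rnorm(n, 35, 10))
  d$bmi <- d$weight / (d$height / 100)^2
  for (cn in stancecurve:::PARAM_COLUMNS)
    d[[cn]] <- 100 - 0.01 * d$weight + stats::rnorm(n, 0, 1)
  fits <- fit_all(d)
  expect_s3_class(fits, "stance_fits")
  expect_length(fits, 18)
  tab <- format_fit_table(fits)
  expect_equal(nrow(tab), 9)
  full <- as.data.frame(fits)
  for (i in seq_len(nrow(tab))) {
    fm <- fits[[paste(tab$parameter[i], "main", sep = ".")]]
    for (term in c("age", "height", "weight", "grip")) {
      shown <- tab[[term]][i] != ""
      pv <- fm$coefficients$p[fm$coefficients$term == term]
      expect_equal(shown, pv < 0.05)
    }
  }
})

test_that("planted coefficients are recovered within their CIs (direct cohort)", {
  spec <- cohort_spec(n_subjects = 200, seed = 96)
  planted <- spec$planted
  n_rep <- 100
  cover <- matrix(0L, 3, 4, dimnames = dimnames(planted))
  set.seed(96)
  for (r in seq_len(n_rep)) {
    d <- sample_cohort(spec, seed = NULL)
    ctr <- sweep(as.matrix(d[, c("age", "height", "weight", "grip")]), 2,
                 c(spec$age$mean, spec$height$mean, spec$weight$mean,
                   spec$grip$mean))
    for (k in 1:3) {
      dep <- rownames(planted)[k]
      d[[dep]] <- spec$baselines[k] + as.numeric(ctr %*% planted[k, ]) +
        stats::rnorm(200, 0, spec$resid_sd[k])
    }
    for (k in 1:3) {
      f <- fit_model(d, rownames(planted)[k], "main")
      tcrit <- stats::qt(0.975, df = 200 - 4 - 1)
      lo <- f$coefficients$estimate - tcrit * f$coefficients$se
      hi <- f$coefficients$estimate + tcrit * f$coefficients$se
      hit <- planted[k, f$coefficients$term] >= lo &
        planted[k, f$coefficients$term] <= hi
      cover[k, f$coefficients$term] <- cover[k, f$coefficients$term] +
        as.integer(hit)
    }
  }
  # every nonzero planted coefficient covered in >= 90% of replicates
  nz <- which(planted != 0, arr.ind = TRUE)
  for (j in seq_len(nrow(nz)))
    expect_gte(cover[nz[j, 1], nz[j, 2]], 0.9 * n_rep)
})

test_that("null cohorts show the nominal 5% false-positive rate", {
  set.seed(97)
  n_rep <- 200
  sig <- 0L
  total <- 0L
  for (r in seq_len(n_rep)) {
    n <- 40
    d <- data.frame(age = stats::rnorm(n, 45, 15),
                    height = stats::rnorm(n, 172, 10),
                    weight = stats::rnorm(n, 80, 20),
                    grip = stats::rnorm(n, 35, 10))
    d$bmi <- d$weight / (d$height / 100)^2
    d$y <- stats::rnorm(n)
    for (m in c("main", "bmi")) {
      f <- fit_model(d, "y", m)
      sig <- sig + sum(f$coefficients$p < 0.05)
      total <- total + nrow(f$coefficients)
    }
  }
  bounds <- stats::qbinom(c(0.005, 0.995), total, 0.05)
  expect_gte(sig, bounds[1])
  expect_lte(sig, bounds[2])
})

test_that("subject_table joins aggregates with profiles", {
  profiles <- data.frame(subject_id = c("a", "b"), age = c(30, 40),
                         height = c(170, 180), weight = c(70, 80),
                         bmi = c(24.2, 24.7), grip = c(30, 40))
  aggs <- list(make_agg("a", rep(1, 100)), make_agg("b", rep(2, 100)))
  st <- subject_table(aggs, profiles)
  expect_equal(nrow(st), 2)
  expect_equal(st$age, c(30, 40))
  expect_true(all(stancecurve:::PARAM_COLUMNS %in% names(st)))
})
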