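test_that("kernel weights follow the truncated Gaussian closed form", {
  w <- gaussian_kernel(filter_config(sigma = 3, kernel_size = 7))
  raw <- exp(-(-3:3)^2 / 18)
  expect_equal(w, raw / sum(raw))
  expect_equal(sum(w), 1)
  # center weight of the unit impulse response:
  # 1 / (1 + 2(e^{-1/18} + e^{-4/18} + e^{-9/18}))
  expect_equal(w[4], 0.175240, tolerance = 1e-5)
})

test_that("filtering preserves constants, impulse center, and ramp interiors", {
  expect_equal(gaussian_filter_curve(rep(3.7, 100)), rep(3.7, 100))

  imp <- numeric(100)
  imp[51] <- 1
  w <- gaussian_kernel()
  expect_equal(gaussian_filter_curve(imp)[51], w[4])

  ramp <- seq(0, 99)
  fr <- gaussian_filter_curve(ramp)
  expect_equal(fr[4:97], ramp[4:97], tolerance = 1e-12)
})

test_that("filtering preserves the curve mean on constant and periodic fixtures", {
  expect_equal(mean(gaussian_filter_curve(rep(5, 100))), 5, tolerance = 1e-9)
  v <- 80 + 30 * cos(2 * pi * (0:99) / 198)  # even about both boundaries
  expect_equal(mean(gaussian_filter_curve(v)), mean(v), tolerance = 1e-9)
})

test_that("candidate scan finds interior extrema and plateau centers", {
  expect_equal(nrow(find_candidates(seq(1, 100))), 0)

  v <- index_m_curve(20, 50, 80)
  cand <- find_candidates(v)
  expect_equal(cand$index[cand$polarity == "max"], c(20, 80))
  expect_equal(cand$index[cand$polarity == "min"], 50)

  vp <- c(seq(0, 40, length.out = 41), 40, 40, seq(39, 0, length.out = 57))
  cand <- find_candidates(vp)
  expect_equal(cand$index[cand$polarity == "max"], 41)  # center of 40-42
})

test_that("time plausibility removes candidates near the edges", {
  v <- index_m_curve(40, 55, 80)
  v[1:8] <- v[1:8] + c(0, 2, 4, 2, 0, 0, 0, 0)  # spurious max at index 2
  fc <- gaussian_filter_curve(v)
  cand <- find_candidates(fc)
  expect_true(any(cand$index < 10))
  res <- disambiguate(cand, fc)
  expect_false(is_rejection(res))
  expect_true("time_plausibility" %in% res$strategies_applied)
  # survivors are exactly the interior candidates
  inner <- cand[cand$index >= 10 & cand$index < 90, ]
  expect_equal(c(res$i_fz2, res$i_fz4),
               sort(inner$index[inner$polarity == "max"]))
  expect_equal(res$i_fz3, inner$index[inner$polarity == "min"])
})

test_that("pool filtering keeps the strongest candidate of a tight cluster", {
  fc <- index_m_curve(40, 60, 80)
  cand <- data.frame(index = c(38L, 40L, 80L, 60L),
                     polarity = c("max", "max", "max", "min"),
                     filtered_value = c(1.01, 1.04, 1.00, 0.70))
  res <- disambiguate(cand, fc)
  expect_false(is_rejection(res))
  expect_equal(res$i_fz2, 40)
  expect_true("pool_filtering" %in% res$strategies_applied)
})

test_that("an already unambiguous candidate set passes through untouched", {
  v <- index_m_curve(25, 50, 75)
  fc <- gaussian_filter_curve(v)
  cand <- find_candidates(fc)
  expect_equal(nrow(cand), 3)
  res <- disambiguate(cand, fc)
  expect_false(is_rejection(res))
  expect_length(res$strategies_applied, 0)
  expect_equal(c(res$i_fz2, res$i_fz3, res$i_fz4),
               cand$index[order(cand$index)])
})

test_that("irregular candidate counts are rejected as non-step events", {
  # three far-apart maxima survive every strategy -> non-step
  h <- function(x) 0.5 * (1 + cos(pi * pmin(abs(x), 1)))
  i <- 0:99
  v <- 50 + 40 * h((i - 20) / 12) + 40 * h((i - 50) / 12) + 40 * h((i - 80) / 12)
  res <- locate_extrema(v)
  expect_true(is_rejection(res))
  expect_equal(res$rule, "candidate_count")

  expect_true(is_rejection(locate_extrema(rep(1, 100))))
  expect_equal(locate_extrema(rep(1, 100))$rule, "no_candidates")
})

test_that("a minimum outside the two maxima is rejected", {
  cand <- data.frame(index = c(30L, 60L, 20L),
                     polarity = c("max", "max", "min"),
                     filtered_value = c(1.1, 1.05, 0.7))
  res <- disambiguate(cand, index_m_curve())
  expect_true(is_rejection(res))
  expect_equal(res$rule, "ordering")
})

test_that("extremum values come from the unfiltered curve at exact indices", {
  # cosine curve: locally even around every extremum, so smoothing leaves
  # the extremum positions untouched and the unfiltered read-back is exact
  v <- 92.5 - 17.5 * cos(2 * pi * (0:99) / 50)
  res <- locate_extrema(v)
  expect_false(is_rejection(res))
  expect_equal(c(res$i_fz2, res$i_fz3, res$i_fz4), c(25, 50, 75))
  expect_equal(res$fz2, 110, tolerance = 1e-6)
  expect_equal(res$fz3, 75, tolerance = 1e-6)
  expect_equal(res$fz4, 110, tolerance = 1e-6)

  # on an asymmetric-curvature M-curve the filter may shift the argmax by
  # an index, but the values are still read from the unfiltered curve
  v2 <- index_m_curve(25, 50, 75, fz2 = 110, fz3 = 75, fz4 = 105)
  res2 <- locate_extrema(v2)
  expect_false(is_rejection(res2))
  expect_equal(res2$fz2, v2[res2$i_fz2 + 1])
  expect_equal(res2$fz4, v2[res2$i_fz4 + 1])
  expect_lt(abs(res2$i_fz2 - 25), 2)
  expect_lt(abs(res2$i_fz4 - 75), 2)
})

test_that("extremum indices are robust to sensor-level noise", {
  set.seed(77)
  v <- index_m_curve(25, 50, 75)
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    res <- locate_extrema(v + stats::rnorm(100, 0, 0.5))
    if (!is_rejection(res) &&
        abs(res$i_fz2 - 25) <= 3 && abs(res$i_fz3 - 50) <= 3 &&
        abs(res$i_fz4 - 75) <= 3)
      hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * n_rep)
})

test_that("accepted extrema are always ordered Fz2 < Fz3 < Fz4", {
  set.seed(78)
  for (r in 1:100) {
    v <- random_smooth_curve()
    res <- locate_extrema(v)
    if (!is_rejection(res)) {
      expect_lt(res$i_fz2, res$i_fz3)
      expect_lt(res$i_fz3, res$i_fz4)
      # value ordering holds on the filtered curve that selected them
      fc <- gaussian_filter_curve(v)
      expect_lte(fc[res$i_fz3 + 1], fc[res$i_fz2 + 1])
      expect_lte(fc[res$i_fz3 + 1], fc[res$i_fz4 + 1])
    }
  }
})

test_that("filter config validation", {
  expect_error(filter_config(sigma = 0), "positive")
  expect_error(filter_config(kernel_size = 6), "odd")
})
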