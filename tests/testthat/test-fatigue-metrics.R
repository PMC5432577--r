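# RMS, MVC normalization, trend fitting and subject-level aggregation.

test_that("segment RMS matches closed forms", {
  expect_equal(segment_rms(rep(3, 100)), 3)
  expect_equal(segment_rms(rep(c(-2, 2), 50)), 2)
  t <- (0:1999) / 2000
  expect_equal(segment_rms(sin(2 * pi * 10 * t)), 1 / sqrt(2),
               tolerance = 1e-9)
  # spans are 0-based half-open
  x <- c(rep(0, 10), rep(5, 10))
  expect_equal(segment_rms(x, span = c(10, 20)), 5)
  expect_error(segment_rms(x, span = c(5, 5)), "empty")
})

test_that("MVC normalization is a plain ratio with channel lookup", {
  ref <- structure(list(rms = c(L5_left = 100, L5_right = 80),
                        window = c(2, 5)), class = "mvc_reference")
  expect_equal(normalize_rms(100, ref, "L5_left"), 1.0)
  expect_equal(normalize_rms(121, ref, "L5_left"), 1.21)
  expect_equal(normalize_rms(0, ref, "L5_right"), 0)
  expect_error(normalize_rms(50, ref, "L1_left"), "missing")
})

test_that("trend fitting recovers exact lines and matches the OLS oracle", {
  t <- seq(2, 98, by = 4)
  tr <- fit_trend(t, 1.0 - 0.002 * t)
  expect_equal(tr$initial_value, 1.0, tolerance = 1e-12)
  expect_equal(tr$normalized_slope, -0.2, tolerance = 1e-9)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)

  tr0 <- fit_trend(t, rep(2.5, length(t)))
  expect_equal(tr0$slope, 0, tolerance = 1e-12)

  set.seed(1)
  y <- 3 + 0.05 * t + rnorm(length(t))
  tr2 <- fit_trend(t, y)
  o <- ols_oracle(t, y)
  expect_equal(tr2$initial_value, unname(o["intercept"]), tolerance = 1e-12)
  expect_equal(tr2$slope, unname(o["slope"]), tolerance = 1e-12)
})

test_that("trend fitting rejects degenerate series", {
  expect_error(fit_trend(1:4, 1:4), "at least 5")
  expect_error(fit_trend(rep(2, 6), rnorm(6)), "degenerate")
  tr <- fit_trend(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2))  # intercept 0
  expect_true(is.na(tr$normalized_slope))
})

test_that("normalized slope is invariant to scaling, raw parameters equivariant", {
  t <- seq(2, 98, by = 4)
  set.seed(2)
  y <- 1 + 0.001 * t + rnorm(length(t), sd = 0.05)
  a <- fit_trend(t, y)
  b <- fit_trend(t, 7.3 * y)
  expect_equal(b$initial_value, 7.3 * a$initial_value)
  expect_equal(b$slope, 7.3 * a$slope)
  expect_equal(b$normalized_slope, a$normalized_slope)
})

test_that("initial value is the extrapolated intercept at exercise onset", {
  # drop the first cycles as the segmentation does: intercept still at t = 0
  t_full <- seq(2, 98, by = 4)
  keep <- t_full >= 10 & t_full <= 90
  tr <- fit_trend(t_full[keep], 2.0 - 0.004 * t_full[keep])
  expect_equal(tr$initial_value, 2.0, tolerance = 1e-9)
  expect_gt(tr$initial_value, max(2.0 - 0.004 * t_full[keep]))
})

test_that("slope recovery from noisy series matches the estimator's precision", {
  t <- seq(2, 82, by = 4)    # 21 retained cycles
  truth <- -0.2              # %/s
  rec <- sapply(1:100, function(s) {
    set.seed(600 + s)
    y <- 1 + truth / 100 * t + rnorm(length(t), sd = 0.05)
    fit_trend(t, y)$normalized_slope
  })
  expect_lt(abs(median(rec) - truth), 0.03)
  expect_lt(sd(rec), 0.08)
})

make_trends <- function(slopes, initials = rep(1, 6)) {
  ch <- default_channels()
  do.call(rbind, lapply(c("concentric", "eccentric"), function(ph)
    do.call(rbind, lapply(c("rms", "imdf"), function(par)
      data.frame(channel = ch$label, level = ch$level, side = ch$side,
                 phase = ph, parameter = par,
                 initial_value = initials, slope = slopes / 100,
                 normalized_slope = slopes, n_points = 21,
                 r_squared = 0.5, stringsAsFactors = FALSE)))))
}

test_that("aggregation is idempotent on identical channels", {
  agg <- aggregate_subject(make_trends(rep(-0.1, 6), rep(1.2, 6)))
  expect_true(all(abs(agg$rows$initial_value - 1.2) < 1e-12))
  expect_true(all(abs(agg$rows$normalized_slope + 0.1) < 1e-12))
})

test_that("the all-electrode row is the mean of the three level rows", {
  set.seed(3)
  tr <- make_trends(rnorm(6), runif(6, 0.5, 1.5))
  agg <- aggregate_subject(tr)
  for (par in c("rms", "imdf")) for (ph in c("concentric", "eccentric")) {
    r <- agg$rows[agg$rows$parameter == par & agg$rows$phase == ph, ]
    expect_equal(r$initial_value[r$row == "all"],
                 mean(r$initial_value[r$row %in% c("L1", "L2", "L5")]))
    expect_equal(r$normalized_slope[r$row == "all"],
                 mean(r$normalized_slope[r$row %in% c("L1", "L2", "L5")]))
  }
})

test_that("the most negative electrode is selected per parameter and phase", {
  tr <- make_trends(c(-0.05, -0.3, 0.1, 0.2, -0.1, 0))
  # steepest negative slope sits on the second channel (L1_right)
  agg <- aggregate_subject(tr)
  worst <- agg$rows[agg$rows$row == "most_negative", ]
  expect_true(all(worst$channel == "L1_right"))
  expect_true(all(worst$normalized_slope == -0.3))
})

test_that("aggregation requires the full montage", {
  tr <- make_trends(rep(0, 6))
  expect_error(aggregate_subject(tr[tr$channel != "L2_left", ]), "L2_left")
})

test_that("concentric/eccentric ratio arithmetic", {
  expect_equal(conc_ecc_ratio(1, 1), 1)
  expect_equal(round(conc_ecc_ratio(1.21, 0.68), 2), 1.78)
  expect_equal(round(conc_ecc_ratio(1.22, 0.63), 2), 1.94)
  expect_error(conc_ecc_ratio(1, 0), "undefined")
})
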