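# Synthetic generator: determinism, kinematic construction, amplitude and
# spectral calibration, ground-truth bookkeeping.

one_channel <- data.frame(level = "L5", side = "left", label = "L5_left",
                          stringsAsFactors = FALSE)

test_that("identical seed and config give bit-identical output", {
  cfg <- synthetic_config(n_cycles = 2, cycle_duration = 2,
                          channels = one_channel, seed = 11)
  a <- generate_semg(cfg)
  b <- generate_semg(cfg)
  expect_identical(a$cyclic$semg, b$cyclic$semg)
  expect_identical(a$cyclic$accel_z, b$cyclic$accel_z)
  expect_identical(a$mvc80$semg, b$mvc80$semg)
  cfg2 <- synthetic_config(n_cycles = 2, cycle_duration = 2,
                           channels = one_channel, seed = 12)
  expect_false(identical(generate_semg(cfg2)$cyclic$semg, a$cyclic$semg))
})

test_that("kinematics construct the paced cyclic movement", {
  cfg <- synthetic_config(n_cycles = 25, cycle_duration = 4)
  kin <- generate_kinematics(cfg)
  expect_equal(length(kin$t_s), 100 * cfg$accel_rate)
  # 25 maxima at ~40 degrees: count samples at the flexion peak per cycle
  peaks <- sum(diff(sign(diff(kin$angle_deg))) == -2)
  expect_equal(peaks, 25)
  expect_equal(max(kin$angle_deg), 40, tolerance = 1e-6)
  expect_equal(min(kin$angle_deg), 0, tolerance = 1e-6)
  # acc = sin(angle): 0 deg -> 0 g, 40 deg -> 0.643 g
  expect_equal(kin$acc_z_g[1], 0, tolerance = 1e-12)
  expect_equal(max(kin$acc_z_g), sin(40 * pi / 180), tolerance = 1e-6)
  expect_equal(round(sin(40 * pi / 180), 3), 0.643)
})

test_that("ground-truth boundaries partition the trace with alternating phases", {
  cfg <- synthetic_config(n_cycles = 10, channels = one_channel)
  kin <- generate_kinematics(cfg)
  b <- kin$boundaries
  expect_equal(nrow(b), 20)
  expect_equal(b$t_start_s[-1], b$t_end_s[-nrow(b)])
  expect_equal(b$t_start_s[1], 0)
  expect_equal(b$t_end_s[nrow(b)], 10 * cfg$cycle_duration)
  expect_true(all(b$phase == rep(c("eccentric", "concentric"), 10)))
})

test_that("angle ranges beyond the arcsine domain are rejected", {
  expect_error(synthetic_config(angle_range = 95), "angle_range")
  expect_error(synthetic_config(angle_range = -5), "angle_range")
})

test_that("segment RMS is calibrated to the configured targets", {
  # drift-free config; empirical RMS averaged over 20 seeds within 3%
  ratios <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_cycles = 2, cycle_duration = 2,
                            channels = one_channel,
                            rms_slope_conc = 0, rms_slope_ecc = 0,
                            imdf_slope_conc = 0, imdf_slope_ecc = 0,
                            noise_floor = 0, seed = 100 + s)
    out <- generate_semg(cfg)
    gt <- out$ground_truth$channel_targets
    fs <- cfg$semg_rate
    sapply(seq_len(nrow(gt)), function(k) {
      i0 <- round(gt$t_start_s[k] * fs) + 1
      i1 <- round(gt$t_end_s[k] * fs)
      sqrt(mean(out$cyclic$semg[i0:i1, 1]^2)) / gt$target_rms_uv[k]
    })
  })
  expect_lt(abs(mean(ratios) - 1), 0.03)
})

test_that("concentric/eccentric amplitude ratio is realized per cycle", {
  rr <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_cycles = 3, channels = one_channel,
                            rms_slope_conc = 0, rms_slope_ecc = 0,
                            noise_floor = 0, seed = 200 + s)
    out <- generate_semg(cfg)
    gt <- out$ground_truth$channel_targets
    fs <- cfg$semg_rate
    rms <- sapply(seq_len(nrow(gt)), function(k) {
      i0 <- round(gt$t_start_s[k] * fs) + 1
      i1 <- round(gt$t_end_s[k] * fs)
      sqrt(mean(out$cyclic$semg[i0:i1, 1]^2))
    })
    mean(rms[gt$phase == "concentric"]) / mean(rms[gt$phase == "eccentric"])
  })
  expect_equal(mean(rr), 1.85, tolerance = 0.03)
})

test_that("stationary spectral median is calibrated to imdf0", {
  # periodogram cumulative-sum oracle, 10 s stationary segments, 20 seeds
  for (f0 in c(53, 70)) {
    meds <- sapply(1:20, function(s) {
      set.seed(300 + s)
      pgram_median(semgfatigue:::shaped_noise(20000, 2000, f0, 100), 2000)
    })
    expect_lt(abs(mean(meds) - f0), 2)
  }
})

test_that("imposed spectral drift follows the configured linear law", {
  # closed form: -0.00108/s over 100 s compresses the median by 10.8%
  cfg <- synthetic_config(imdf_slope_conc = -0.00108, imdf_slope_ecc = -0.00108,
                          channels = one_channel, seed = 1)
  out <- generate_semg(cfg)
  gt <- out$ground_truth$channel_targets
  conc <- gt[gt$phase == "concentric", ]
  drop_frac <- 1 - conc$target_imdf_hz[nrow(conc)] / conc$target_imdf_hz[1]
  # concentric mid-times run from 3 s to 99 s (96 s apart)
  expect_equal(drop_frac, 0.00108 * 96 / (1 - 0.00108 * 3), tolerance = 1e-10)
  # ~10.8% compression over the 100 s exercise, slightly less between
  # the first and last half-cycle midpoints
  expect_equal(drop_frac, 0.104, tolerance = 0.005)
})

test_that("a drift that leaves the synthesizable band or crosses zero errors out", {
  # a median target near Nyquist cannot be synthesized inside the
  # emulated 20-450 Hz acquisition band
  cfg <- synthetic_config(n_cycles = 25, channels = one_channel,
                          imdf0 = c(L1 = 53, L2 = 57, L5 = 900),
                          imdf_slope_conc = 0.005, imdf_slope_ecc = 0.005)
  expect_error(generate_semg(cfg), "band")
  cfg2 <- synthetic_config(n_cycles = 25, channels = one_channel,
                           rms_slope_conc = -0.02, rms_slope_ecc = -0.02)
  expect_error(generate_semg(cfg2), "amplitude")
})

test_that("the MVC reference recording matches its stored ground truth", {
  cfg <- synthetic_config(n_cycles = 2, cycle_duration = 2,
                          channels = one_channel, seed = 5)
  out <- generate_semg(cfg)
  expect_gte(nrow(out$mvc80$semg) / out$mvc80$semg_rate, 5)
  rms <- sqrt(mean(out$mvc80$semg[, 1]^2))
  expect_equal(rms, out$ground_truth$mvc_rms_uv, tolerance = 0.1)
})
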