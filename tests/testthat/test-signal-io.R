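# Container round trip, schema validation, pre-filtering and the MVC
# amplitude reference.

small_trial <- function(seed = 3) {
  cfg <- synthetic_config(n_cycles = 2, cycle_duration = 2, seed = seed)
  generate_semg(cfg, subject_id = "T01", age = 41, sex = "female")
}

test_that("write then read reproduces a recording bit-exactly", {
  out <- small_trial()
  dir <- withr::local_tempdir()
  write_recording(out$cyclic, dir)
  back <- read_recording(dir)
  expect_identical(back$semg, out$cyclic$semg)
  expect_identical(back$accel_z, out$cyclic$accel_z)
  expect_equal(back$semg_rate, out$cyclic$semg_rate)
  expect_equal(back$accel_rate, out$cyclic$accel_rate)
  expect_equal(back$meta$subject_id, "T01")
  expect_equal(back$meta$age, 41)
  expect_equal(back$meta$sex, "female")
  expect_equal(back$meta$kind, "cyclic")
})

test_that("malformed containers produce schema errors naming the field", {
  out <- small_trial()
  dir <- withr::local_tempdir()
  write_recording(out$cyclic, dir)
  file.remove(file.path(dir, "accel.csv"))
  expect_error(read_recording(dir), "accel")

  dir2 <- withr::local_tempdir()
  write_recording(out$cyclic, dir2)
  semg <- data.table::fread(file.path(dir2, "semg.csv"), data.table = FALSE)
  semg$L5_left <- NULL
  data.table::fwrite(semg, file.path(dir2, "semg.csv"))
  expect_error(read_recording(dir2), "L5_left")

  dir3 <- withr::local_tempdir()
  write_recording(out$cyclic, dir3)
  meta <- jsonlite::read_json(file.path(dir3, "meta.json"))
  meta$semg_rate <- NULL
  jsonlite::write_json(meta, file.path(dir3, "meta.json"), auto_unbox = TRUE)
  expect_error(read_recording(dir3), "semg_rate")
})

test_that("recording invariants are enforced", {
  out <- small_trial()
  rec <- out$cyclic
  bad <- rec; colnames(bad$semg)[1] <- "L9_left"
  expect_error(validate_recording(bad), "label")
  bad <- rec; bad$semg_rate <- -1
  expect_error(validate_recording(bad), "semg_rate")
  bad <- rec; bad$meta$kind <- "warmup"
  expect_error(validate_recording(bad), "kind")
  bad <- rec; colnames(bad$semg) <- rep("L5_left", 6)
  expect_error(validate_recording(bad), "unique")
})

test_that("band-pass matches the designed Butterworth response", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  # DC is in the stopband: steady-state output RMS < 1% of the input
  # amplitude (the first/last half second carries the zero-phase filter
  # start-up transient)
  dc <- bandpass_semg(rep(2, length(t)), fs)
  expect_lt(sqrt(mean(dc[(fs / 2):(length(t) - fs / 2)]^2)), 0.02)
  # passband tone: unit 100 Hz sinusoid, gain within [0.99, 1.01]
  y <- bandpass_semg(sin(2 * pi * 100 * t), fs)
  gain <- sqrt(mean(y[2000:6000]^2)) / sqrt(0.5)
  expect_gt(gain, 0.99); expect_lt(gain, 1.01)
  # 900 Hz tone attenuated per the independent magnitude-response oracle;
  # forward-backward application squares the single-pass magnitude
  y9 <- bandpass_semg(sin(2 * pi * 900 * t), fs)
  gain9 <- sqrt(mean(y9[2000:6000]^2)) / sqrt(0.5)
  oracle <- butter_gain(900, fs, 4, 500, "low")^2 *
    butter_gain(900, fs, 4, 20, "high")^2
  expect_equal(gain9, oracle, tolerance = 0.15)
  expect_lt(gain9, 0.01)
})

test_that("filtering is idempotent in the passband sense", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  once <- bandpass_semg(x, fs)
  twice <- bandpass_semg(once, fs)
  a1 <- sqrt(mean(once[2000:6000]^2))
  a2 <- sqrt(mean(twice[2000:6000]^2))
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("rates at or below twice the low-pass cut-off are rejected", {
  expect_error(bandpass_semg(rnorm(100), 1000), "Nyquist")
})

test_that("MVC reference uses exactly the 2-5 s window", {
  out <- small_trial()
  mvc <- out$mvc80
  ref <- mvc_reference(mvc)
  expect_true(all(ref$rms > 0))
  expect_equal(ref$window, c(2, 5))
  # perturbing samples outside [2, 5) leaves the reference unchanged
  fs <- mvc$semg_rate
  tampered <- mvc
  tampered$semg[1:(2 * fs - 1), ] <- 0
  tampered$semg[(5 * fs + 1):nrow(tampered$semg), ] <- 1e6
  expect_identical(mvc_reference(tampered)$rms, ref$rms)
})

test_that("MVC reference recovers known amplitudes", {
  fs <- 2000
  n <- 6 * fs
  t <- (0:(n - 1)) / fs
  chans <- default_channels()
  # unit 100 Hz sinusoid on every channel: RMS = 1/sqrt(2)
  semg <- matrix(sin(2 * pi * 100 * t), n, 6,
                 dimnames = list(NULL, chans$label))
  rec <- new_recording(semg, fs, numeric(6 * 160), 160,
                       list(subject_id = "x", kind = "mvc80"))
  ref <- mvc_reference(rec)
  expect_equal(unname(ref$rms), rep(1 / sqrt(2), 6), tolerance = 1e-3)
  # synthetic MVC recording with a configured target: estimate within 3%
  cfg <- synthetic_config(n_cycles = 2, cycle_duration = 2, mvc_rms = 200,
                          seed = 8)
  out <- generate_semg(cfg)
  est <- mvc_reference(out$mvc80)$rms
  expect_lt(abs(mean(est / 200) - 1), 0.03)  # calibration (channel average)
  expect_lt(max(abs(est / 200 - 1)), 0.10)   # no channel far off
})

test_that("recordings shorter than the MVC window are rejected", {
  fs <- 2000
  semg <- matrix(rnorm(4 * fs * 6), ncol = 6,
                 dimnames = list(NULL, default_channels()$label))
  rec <- new_recording(semg, fs, numeric(10), 160,
                       list(subject_id = "x", kind = "mvc80"))
  expect_error(mvc_reference(rec), "at least 5")
})
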