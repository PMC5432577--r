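# Synthetic trial generator.
#
# The generator emulates the paced cyclic trunk-extension protocol: 25
# cycles of ~4 s spanning 0-40 degrees of flexion, six SEMG channels
# (L1/L2/L5, both sides) at 2 kHz, a lever-arm accelerometer z-axis at
# 160 Hz, phase-dependent amplitude (concentric about 1.85x eccentric),
# linear per-cycle drift of RMS and of spectral median frequency, and an
# 80% MVC reference recording. Ground truth is emitted as a sidecar and is
# never consumed by the analysis pipeline.

#' Synthetic trial configuration
#'
#' Defaults mirror the cyclic back-extension protocol: 25 cycles of 4 s
#' (eccentric 0 to 40 degrees, then concentric back to 0), SEMG at 2000 Hz,
#' accelerometer at 160 Hz, concentric/eccentric amplitude ratio 1.85,
#' baseline noise 0.75 uV RMS, per-level initial median frequencies
#' (L5 70, L2 57, L1 53 Hz) and per-second fractional drifts of RMS and
#' median frequency equal to the cohort-median fatigue indices
#' (RMS +0.13 %/s concentric, 0 eccentric; IMDF -0.11 %/s both phases).
#'
#' @param n_cycles number of movement cycles (>= 1).
#' @param cycle_duration seconds per full cycle.
#' @param angle_range peak trunk flexion in degrees, within [0, 90).
#' @param semg_rate,accel_rate sampling rates in Hz.
#' @param channels data.frame with `level`, `side`, `label` columns.
#' @param rms_conc0 initial concentric RMS target in microvolts.
#' @param conc_ecc_amplitude_ratio initial concentric / eccentric RMS ratio.
#' @param rms_slope_conc,rms_slope_ecc fractional RMS drift per second
#'   (signed; 0.0013 means +0.13 % of the initial value per second).
#' @param imdf0 named numeric: initial spectral median frequency (Hz) per
#'   level (`L1`, `L2`, `L5`), each within (0, `semg_rate`/2).
#' @param imdf_slope_conc,imdf_slope_ecc fractional median-frequency drift
#'   per second (signed).
#' @param noise_floor additive white measurement noise, uV RMS.
#' @param mvc_rms per-channel RMS of the 80\% MVC reference recording (uV).
#'   The default places the initial concentric amplitude at 1.21 of the
#'   MVC reference, the typical normalized level for this exercise.
#' @param mvc_duration MVC recording length, seconds (>= 5 s analysis need).
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cycles = 25, cycle_duration = 4,
                             angle_range = 40,
                             semg_rate = 2000, accel_rate = 160,
                             channels = default_channels(),
                             rms_conc0 = 150,
                             conc_ecc_amplitude_ratio = 1.85,
                             rms_slope_conc = 0.0013, rms_slope_ecc = 0,
                             imdf0 = c(L1 = 53, L2 = 57, L5 = 70),
                             imdf_slope_conc = -0.0011,
                             imdf_slope_ecc = -0.0011,
                             noise_floor = 0.75,
                             mvc_rms = rms_conc0 / 1.21,
                             mvc_duration = 6,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_cycles >= 1, cfg$cycle_duration > 0,
            cfg$semg_rate > 0, cfg$accel_rate > 0,
            cfg$conc_ecc_amplitude_ratio > 0,
            cfg$rms_conc0 > 0, cfg$mvc_rms > 0, cfg$noise_floor >= 0,
            cfg$mvc_duration >= 5)
  if (cfg$angle_range < 0 || cfg$angle_range >= 90)
    stop("angle_range must lie in [0, 90) degrees: ",
         "the arcsine inversion of the accelerometer is ambiguous beyond 90")
  if (!all(c("L1", "L2", "L5") %in% names(cfg$imdf0)))
    stop("imdf0 must be named with levels L1, L2, L5")
  if (any(cfg$imdf0 <= 0) || any(cfg$imdf0 >= cfg$semg_rate / 2))
    stop("imdf0 values must lie in (0, semg_rate/2)")
  invisible(cfg)
}

# --- spectral shape ---------------------------------------------------------

# Two-pole analytic surface-EMG power spectral shape
#   S(f) = fh^4 f^2 / ((f^2 + fl^2) (f^2 + fh^2)^2)
# Unimodal; jointly scaling (fl, fh) scales its median frequency linearly.
emg_shape_psd <- function(f, fl, fh) {
  fh^4 * f^2 / ((f^2 + fl^2) * (f^2 + fh^2)^2)
}

# Analog acquisition band of the emulated SEMG amplifier (20-450 Hz
# hardware band), as smooth cosine ramps. Generated signals carry no
# energy outside it, so the digital 20/500 Hz pre-filter is nearly
# transparent and the configured RMS and median-frequency targets survive
# the conditioning chain.
emg_band_window <- function(f) {
  w <- numeric(length(f))
  lo0 <- 18; lo1 <- 28; hi0 <- 400; hi1 <- 450
  w[f >= lo1 & f <= hi0] <- 1
  ramp_up <- f > lo0 & f < lo1
  w[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - lo0) / (lo1 - lo0)))
  ramp_dn <- f > hi0 & f < hi1
  w[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - hi0) / (hi1 - hi0)))
  w
}

.shape_cache <- new.env(parent = emptyenv())

# Median frequency of the shape, by trapezoidal cumulative integration on
# a fine grid; the f^-4 tail beyond the grid carries negligible mass.
shape_median <- function(fl, fh) {
  f <- seq(0, 2000, by = 0.05)   # band window kills everything past 450 Hz
  s <- emg_shape_psd(f, fl, fh) * emg_band_window(f)
  cs <- cumsum((s[-1] + s[-length(s)]) / 2)
  f[-1][which(cs >= cs[length(cs)] / 2)[1]]
}

# Shape parameters for a target median frequency. The low-side pole is
# pinned at the target median itself, which keeps the sub-20 Hz tail small
# (as in measured surface EMG); the high-side pole is solved so the
# shape's median equals the target. Memoised per target.
shape_params <- function(f_med) {
  if (f_med <= 30 || f_med >= 400)
    stop("median frequency ", round(f_med, 1), " Hz is outside the ",
         "synthesizable acquisition band (30-400 Hz)")
  key <- sprintf("p%.6g", f_med)
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  fh <- stats::uniroot(function(fh) shape_median(f_med, fh) - f_med,
                       lower = f_med / 10, upper = 20 * f_med,
                       tol = 1e-3)$root
  out <- list(fl = f_med, fh = fh)
  .shape_cache[[key]] <- out
  out
}

# Band-shaped Gaussian noise with the given shape poles and theoretical
# RMS, by frequency-domain shaping of white noise.
shaped_noise_poles <- function(n, fs, fl, fh, rms_target) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n     # symmetric two-sided frequency axis
  g <- sqrt(emg_shape_psd(f, fl, fh) * emg_band_window(f))
  g[1] <- 0                        # no DC
  g <- g / sqrt(mean(g^2))         # unit average power gain
  w <- rnorm(n)
  x <- Re(fft(fft(w) * g, inverse = TRUE)) / n
  x * rms_target
}

# Convenience wrapper: shaped noise with theoretical median f_med.
shaped_noise <- function(n, fs, f_med, rms_target) {
  if (f_med >= fs / 2)
    stop("scaled median frequency ", round(f_med, 1),
         " Hz is at or above Nyquist (", fs / 2, " Hz)")
  p <- shape_params(f_med)
  shaped_noise_poles(n, fs, p$fl, p$fh, rms_target)
}

# --- kinematics -------------------------------------------------------------

#' Generate synthetic trunk kinematics and accelerometer trace
#'
#' The trunk angle follows a raised cosine over each full cycle, starting
#' upright (0 degrees), flexing forward to `angle_range` in the first half
#' (eccentric for the extensors) and extending back in the second half
#' (concentric). This concentrates angular acceleration at the movement
#' turnarounds, as in paced human movement. The accelerometer z-axis is the
#' exact inverse of the orientation estimate: acc = g sin(angle).
#'
#' @param config a [synthetic_config()].
#' @return list with `t_s`, `angle_deg`, `acc_z_g` (all at `accel_rate`)
#'   and `boundaries`, a data.frame of ground-truth half-cycle spans
#'   (`cycle_index`, `phase`, `t_start_s`, `t_end_s`, `t_mid_s`).
#' @export
generate_kinematics <- function(config) {
  validate_synthetic_config(config)
  total <- config$n_cycles * config$cycle_duration
  n <- round(total * config$accel_rate)
  t <- (seq_len(n) - 1) / config$accel_rate
  angle <- config$angle_range / 2 *
    (1 - cos(2 * pi * t / config$cycle_duration))
  acc <- sin(angle * pi / 180)
  half <- config$cycle_duration / 2
  cyc <- rep(seq_len(config$n_cycles), each = 2)
  ph <- rep(c("eccentric", "concentric"), config$n_cycles)
  t0 <- (seq_len(2 * config$n_cycles) - 1) * half
  boundaries <- data.frame(cycle_index = cyc, phase = ph,
                           t_start_s = t0, t_end_s = t0 + half,
                           t_mid_s = t0 + half / 2,
                           stringsAsFactors = FALSE)
  list(t_s = t, angle_deg = angle, acc_z_g = acc, boundaries = boundaries)
}

# --- SEMG -------------------------------------------------------------------

#' Generate a synthetic SEMG trial with known ground truth
#'
#' Each half-cycle of each channel is band-shaped Gaussian noise whose
#' theoretical median frequency and RMS follow the configured linear
#' drifts, frozen within the half-cycle at its mid-time (piecewise
#' stationary, matching the per-cycle resolution of the downstream
#' estimates): median = imdf0 (1 + imdf_slope_phase t_mid), RMS =
#' rms_phase0 (1 + rms_slope_phase t_mid), with the phase-specific initial
#' RMS obeying the concentric/eccentric amplitude ratio. Independent white
#' noise of `noise_floor` uV RMS is added. An 80\% MVC reference recording
#' (stationary, >= 5 s) is generated alongside.
#'
#' @param config a [synthetic_config()].
#' @param subject_id,age,sex metadata stored on the recordings.
#' @return list with `cyclic` and `mvc80` (both `semg_recording`) and
#'   `ground_truth`, a sidecar list (half-cycle boundaries, per-channel
#'   targets, imposed slopes) that the pipeline never reads.
#' @export
generate_semg <- function(config, subject_id = "synthetic", age = NA_real_,
                          sex = NA_character_) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  kin <- generate_kinematics(config)
  b <- kin$boundaries
  fs <- config$semg_rate
  rms0 <- c(concentric = config$rms_conc0,
            eccentric = config$rms_conc0 / config$conc_ecc_amplitude_ratio)
  rms_sl <- c(concentric = config$rms_slope_conc,
              eccentric = config$rms_slope_ecc)
  imdf_sl <- c(concentric = config$imdf_slope_conc,
               eccentric = config$imdf_slope_ecc)
  n_total <- round(config$n_cycles * config$cycle_duration * fs)
  chans <- config$channels
  semg <- matrix(0, n_total, nrow(chans),
                 dimnames = list(NULL, chans$label))
  truth_rows <- vector("list", nrow(chans))
  for (ci in seq_len(nrow(chans))) {
    lev <- chans$level[ci]
    f0 <- config$imdf0[[lev]]
    x <- numeric(n_total)
    tgt_rms <- tgt_med <- numeric(nrow(b))
    for (k in seq_len(nrow(b))) {
      i0 <- round(b$t_start_s[k] * fs) + 1L
      i1 <- round(b$t_end_s[k] * fs)
      ph <- b$phase[k]
      tm <- b$t_mid_s[k]
      tgt_rms[k] <- rms0[[ph]] * (1 + rms_sl[[ph]] * tm)
      tgt_med[k] <- f0 * (1 + imdf_sl[[ph]] * tm)
      if (tgt_rms[k] <= 0) stop("configured RMS drift drives amplitude <= 0")
      if (tgt_med[k] <= 0) stop("configured IMDF drift drives median <= 0")
      if (tgt_med[k] >= fs / 2)
        stop("drifted median frequency ", round(tgt_med[k], 1),
             " Hz is at or above Nyquist (", fs / 2, " Hz)")
      # poles are re-solved at each half-cycle's drifted target (memoised),
      # so the generated median follows the linear law exactly even though
      # the acquisition-band window does not move with the drift
      p <- shape_params(tgt_med[k])
      x[i0:i1] <- shaped_noise_poles(i1 - i0 + 1L, fs, p$fl, p$fh, tgt_rms[k])
    }
    semg[, ci] <- x + rnorm(n_total, sd = config$noise_floor)
    truth_rows[[ci]] <- data.frame(channel = chans$label[ci], b,
                                   target_rms_uv = tgt_rms,
                                   target_imdf_hz = tgt_med,
                                   stringsAsFactors = FALSE)
  }
  meta <- list(subject_id = subject_id, kind = "cyclic",
               age = age, sex = sex, seed = config$seed)
  cyclic <- new_recording(semg, fs, kin$acc_z_g, config$accel_rate, meta)

  n_mvc <- round(config$mvc_duration * fs)
  mvc <- matrix(0, n_mvc, nrow(chans), dimnames = list(NULL, chans$label))
  for (ci in seq_len(nrow(chans))) {
    f0 <- config$imdf0[[chans$level[ci]]]
    mvc[, ci] <- shaped_noise(n_mvc, fs, f0, config$mvc_rms) +
      rnorm(n_mvc, sd = config$noise_floor)
  }
  mvc_meta <- modifyList(meta, list(kind = "mvc80"))
  mvc80 <- new_recording(mvc, fs,
                         numeric(round(config$mvc_duration * config$accel_rate)),
                         config$accel_rate, mvc_meta)

  ground_truth <- list(
    boundaries = b,
    channel_targets = do.call(rbind, truth_rows),
    rms_initial_uv = rms0,
    rms_slope_frac_per_s = rms_sl,
    imdf_initial_hz = as.list(config$imdf0),
    imdf_slope_frac_per_s = imdf_sl,
    conc_ecc_amplitude_ratio = config$conc_ecc_amplitude_ratio,
    mvc_rms_uv = config$mvc_rms,
    normalized_slope_pct_per_s = list(
      rms_concentric = 100 * config$rms_slope_conc,
      rms_eccentric = 100 * config$rms_slope_ecc,
      imdf_concentric = 100 * config$imdf_slope_conc,
      imdf_eccentric = 100 * config$imdf_slope_ecc),
    seed = config$seed)
  list(cyclic = cyclic, mvc80 = mvc80, ground_truth = ground_truth)
}

#' Simulate one subject (cyclic trial + MVC reference)
#'
#' Thin wrapper over [generate_semg()] that stamps subject metadata.
#'
#' @inheritParams generate_semg
#' @param config a [synthetic_config()]; its `seed` drives all randomness.
#' @return as [generate_semg()].
#' @export
simulate_subject <- function(config, subject_id, age = NA_real_,
                             sex = NA_character_) {
  generate_semg(config, subject_id = subject_id, age = age, sex = sex)
}

#' Write a simulated subject to disk
#'
#' Lays out `<dir>/cyclic/`, `<dir>/mvc80/` (trial containers) and
#' `<dir>/ground_truth.json` (sidecar, not read by the pipeline).
#'
#' @param trial_set output of [simulate_subject()].
#' @param dir subject directory to create.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(trial_set, dir) {
  write_recording(trial_set$cyclic, file.path(dir, "cyclic"))
  write_recording(trial_set$mvc80, file.path(dir, "mvc80"))
  jsonlite::write_json(trial_set$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
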