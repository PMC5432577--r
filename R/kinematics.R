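# Accelerometer-driven kinematics and cycle segmentation.
#
# The lever-arm accelerometer z-axis is a proxy for trunk orientation:
# alpha = asin(acc / g). Angular velocity comes from an 8th-order 1 Hz
# zero-phase Butterworth low-pass of the angle followed by a central first
# difference. Cycles are delimited by alternating angle minima (~0 deg) and
# maxima (~full flexion); the rising half is eccentric (extensors lengthen
# while resisting), the falling half concentric.

#' Trunk angle from accelerometer z-axis
#'
#' alpha = asin(acc / g) in degrees. Ratios slightly outside [-1, 1]
#' (within `tol`) are clamped with a warning; larger excursions indicate
#' sensor miscalibration and are an error.
#'
#' @param acc acceleration along z (same units as `g_const`; with `acc` in
#'   units of g use the default `g_const = 1`).
#' @param g_const gravitational acceleration in the units of `acc`.
#' @param tol clamping tolerance on |acc/g| beyond 1.
#' @return angle in degrees, in [-90, 90].
#' @export
trunk_angle <- function(acc, g_const = 1, tol = 0.05) {
  if (any(!is.finite(acc))) stop("accelerometer trace contains non-finite values")
  r <- acc / g_const
  over <- abs(r) > 1
  if (any(abs(r) > 1 + tol))
    stop("acceleration exceeds gravity by more than ", 100 * tol,
         "% (max |acc/g| = ", round(max(abs(r)), 3),
         "): sensor miscalibration")
  if (any(over)) {
    warning(sum(over), " sample(s) with |acc/g| in (1, 1+tol] clamped to +/-1")
    r <- pmin(pmax(r, -1), 1)
  }
  asin(r) * 180 / pi
}

#' Low-pass filtered angle (1 Hz, 8th order, zero phase)
#' @keywords internal
smooth_angle <- function(angle_deg, rate, cutoff_hz = 1, order = 8) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  zp_filtfilt(bf, angle_deg, pad = round(3 * rate / cutoff_hz),
              restore_trend = TRUE)
}

#' Angular velocity from an angle trace
#'
#' Low-pass filters the angular displacement (8th-order Butterworth, 1 Hz
#' cut-off, applied forward-backward) and takes the central first
#' difference scaled by the sampling rate.
#'
#' @param angle_deg angle trace in degrees.
#' @param rate sampling rate in Hz (> 2 Hz).
#' @param cutoff_hz,order low-pass parameters.
#' @return velocity in degrees/s, same length as the input.
#' @export
angular_velocity <- function(angle_deg, rate, cutoff_hz = 1, order = 8) {
  if (rate <= 2) stop("sampling rate must exceed 2 Hz")
  if (length(angle_deg) < 3 * rate)
    stop("angle trace shorter than the 3 s filter warm-up")
  af <- smooth_angle(angle_deg, rate, cutoff_hz, order)
  central_diff(af) * rate
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Build a kinematics trace from an accelerometer recording
#'
#' @param acc_z accelerometer z-axis in g.
#' @param rate accelerometer sampling rate in Hz.
#' @param g_const gravitational acceleration in the units of `acc_z`.
#' @return data.frame of class `kinematics_trace`: `t_s`, `acc_g`,
#'   `angle_deg` (raw arcsine), `angle_filt_deg` (1 Hz low-passed),
#'   `velocity_deg_s`, `accel_deg_s2`; the rate is kept as attribute `rate`.
#' @export
kinematics_trace <- function(acc_z, rate, g_const = 1) {
  angle <- trunk_angle(acc_z, g_const)
  if (length(angle) < 3 * rate)
    stop("angle trace shorter than the 3 s filter warm-up")
  af <- smooth_angle(angle, rate)
  vel <- central_diff(af) * rate
  acc_ang <- central_diff(vel) * rate
  out <- data.frame(t_s = (seq_along(acc_z) - 1) / rate, acc_g = acc_z,
                    angle_deg = angle, angle_filt_deg = af,
                    velocity_deg_s = vel, accel_deg_s2 = acc_ang)
  attr(out, "rate") <- rate
  class(out) <- c("kinematics_trace", "data.frame")
  out
}

# Alternating extrema (minima ~ upright, maxima ~ full flexion) on the
# filtered angle. Peaks separated by at least min_sep samples; runs of
# same-type extrema are collapsed to the most extreme one. Boundary
# samples count as extrema so a trace that starts or ends mid-posture is
# still delimited.
find_extrema <- function(af, min_sep) {
  rng <- range(af)
  if (diff(rng) < 1e-6) return(data.frame(idx = integer(), type = character()))
  midpoint <- mean(rng)
  pk_max <- pracma::findpeaks(af, minpeakdistance = min_sep,
                              minpeakheight = midpoint)
  pk_min <- pracma::findpeaks(-af, minpeakdistance = min_sep,
                              minpeakheight = -midpoint)
  ext <- data.frame(idx = integer(), type = character())
  if (!is.null(pk_max))
    ext <- rbind(ext, data.frame(idx = pk_max[, 2], type = "max"))
  if (!is.null(pk_min))
    ext <- rbind(ext, data.frame(idx = pk_min[, 2], type = "min"))
  n <- length(af)
  if (af[1] < midpoint) ext <- rbind(ext, data.frame(idx = 1L, type = "min"))
  else ext <- rbind(ext, data.frame(idx = 1L, type = "max"))
  if (af[n] < midpoint) ext <- rbind(ext, data.frame(idx = n, type = "min"))
  else ext <- rbind(ext, data.frame(idx = n, type = "max"))
  ext <- ext[order(ext$idx), ]
  # collapse consecutive same-type extrema to the most extreme
  keep <- logical(nrow(ext))
  i <- 1
  while (i <= nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext$type[j + 1] == ext$type[i]) j <- j + 1
    block <- i:j
    vals <- af[ext$idx[block]]
    best <- block[if (ext$type[i] == "max") which.max(vals) else which.min(vals)]
    keep[best] <- TRUE
    i <- j + 1
  }
  ext[keep, , drop = FALSE]
}

#' Segment a trial into labeled concentric/eccentric spans
#'
#' Detects alternating angle minima and maxima on the 1 Hz-filtered angle
#' (minimum peak separation `min_peak_dist_s`), labels rising half-cycles
#' eccentric and falling half-cycles concentric, and within each half-cycle
#' retains the centered window of `window_s` seconds. Half-cycles whose
#' window contains angular acceleration with magnitude above the
#' `accel_quantile` quantile of the whole trial's |angular acceleration|
#' are flagged excluded (disproportionally large acceleration), as are the
#' first and last `omit_edge` cycles. Spans are expressed on the SEMG
#' sample clock as 0-based half-open intervals.
#'
#' @param kin a [kinematics_trace()].
#' @param semg_rate SEMG sampling rate in Hz.
#' @param window_s retained window length per half-cycle, seconds.
#' @param accel_quantile trial-relative exclusion threshold quantile.
#' @param omit_edge cycles flagged excluded at each end.
#' @param min_cycles minimum retained cycles; fewer is an error.
#' @param min_peak_dist_s minimum separation between extrema, seconds.
#' @return data.frame with `cycle_index`, `phase`, `t_start_s`, `t_end_s`,
#'   `t_mid_s`, `duration_s`, `start_sample`, `end_sample` (0-based,
#'   half-open, SEMG clock), `excluded`, `reason`.
#' @export
segment_cycles <- function(kin, semg_rate, window_s = 1.0,
                           accel_quantile = 0.9, omit_edge = 2,
                           min_cycles = 15, min_peak_dist_s = 1.6) {
  rate <- attr(kin, "rate")
  ext <- find_extrema(kin$angle_filt_deg, max(1L, round(min_peak_dist_s * rate)))
  segs <- NULL
  if (nrow(ext) >= 3) {
    thr <- quantile(abs(kin$accel_deg_s2), accel_quantile, names = FALSE)
    rows <- list()
    cycle <- 0L
    for (k in seq_len(nrow(ext) - 1)) {
      i0 <- ext$idx[k]; i1 <- ext$idx[k + 1]
      phase <- if (ext$type[k] == "min") "eccentric" else "concentric"
      if (phase == "eccentric") cycle <- cycle + 1L
      if (cycle == 0L) next       # leading concentric before the first minimum
      dur <- (i1 - i0) / rate
      wc <- min(window_s, dur)
      t_mid <- (kin$t_s[i0] + kin$t_s[i1]) / 2
      t_start <- t_mid - wc / 2
      t_end <- t_mid + wc / 2
      w0 <- max(1L, round(t_start * rate) + 1L)
      w1 <- min(nrow(kin), round(t_end * rate))
      excluded <- FALSE; reason <- ""
      if (any(abs(kin$accel_deg_s2[w0:w1]) > thr)) {
        excluded <- TRUE; reason <- "acceleration"
      }
      rows[[length(rows) + 1]] <- data.frame(
        cycle_index = cycle, phase = phase,
        t_start_s = t_start, t_end_s = t_end, t_mid_s = t_mid,
        duration_s = wc,
        start_sample = round(t_start * semg_rate),
        end_sample = round(t_end * semg_rate),
        excluded = excluded, reason = reason, stringsAsFactors = FALSE)
    }
    if (length(rows)) segs <- do.call(rbind, rows)
  }
  if (is.null(segs) || nrow(segs) == 0)
    stop("fewer than min_cycles (", min_cycles, ") cycles detected: ",
         "no movement extrema found")
  # a cycle needs both halves; drop a trailing lone eccentric half
  full <- table(factor(segs$phase, c("eccentric", "concentric")),
                segs$cycle_index)
  complete <- as.integer(colnames(full))[full["eccentric", ] == 1 &
                                           full["concentric", ] == 1]
  segs <- segs[segs$cycle_index %in% complete, , drop = FALSE]
  segs$cycle_index <- match(segs$cycle_index, sort(unique(segs$cycle_index)))
  n_cyc <- max(segs$cycle_index)
  edge <- segs$cycle_index <= omit_edge | segs$cycle_index > n_cyc - omit_edge
  segs$reason[edge & !segs$excluded] <- "edge"
  segs$reason[edge & segs$excluded] <- paste0(segs$reason[edge & segs$excluded],
                                              "+edge")
  segs$excluded <- segs$excluded | edge
  retained <- unique(segs$cycle_index[!segs$excluded])
  n_ret <- sum(tapply(!segs$excluded, segs$cycle_index, all))
  if (n_ret < min_cycles)
    stop("fewer than min_cycles (", min_cycles, ") cycles retained (",
         n_ret, "): inconsistent biomechanics or too short a trial")
  rownames(segs) <- NULL
  segs
}

#' Convert a time span to a sample span on another clock
#'
#' 0-based, half-open convention throughout.
#'
#' @param t_start_s,t_end_s span boundaries in seconds.
#' @param rate target sampling rate in Hz.
#' @return integer vector `c(start_sample, end_sample)`.
#' @export
span_samples <- function(t_start_s, t_end_s, rate) {
  c(round(t_start_s * rate), round(t_end_s * rate))
}
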