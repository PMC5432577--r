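# Per-cycle fatigue indices.
#
# For every retained concentric/eccentric segment and every electrode we
# compute the RMS amplitude (normalized to the 80% MVC reference) and the
# segment IMDF. Each channel x phase series is summarized by an ordinary
# least-squares line against segment mid-time measured from exercise
# onset: the intercept is the "initial value" and the slope, expressed as
# percent of the initial value per second, is the fatigue index. Electrode
# aggregation follows the three-level reporting scheme: sides averaged
# within level, levels L1/L2/L5, their mean ("all electrodes") and the
# single electrode with the most negative normalized slope.

#' RMS amplitude over a sample span
#'
#' @param x numeric samples.
#' @param span optional 0-based half-open `c(start, end)` sample interval;
#'   default the whole vector.
#' @return sqrt(mean(x^2)) over the span.
#' @export
segment_rms <- function(x, span = NULL) {
  if (!is.null(span)) {
    if (span[2] <= span[1]) stop("empty sample span")
    x <- x[(span[1] + 1):span[2]]
  }
  if (!length(x)) stop("empty sample span")
  sqrt(mean(x^2))
}

#' Normalize an RMS value by the MVC reference
#'
#' @param rms RMS in microvolts.
#' @param mvc an `mvc_reference` from [mvc_reference()].
#' @param channel channel label present in the reference.
#' @return unitless ratio rms / mvc_rms(channel).
#' @export
normalize_rms <- function(rms, mvc, channel) {
  if (!channel %in% names(mvc$rms))
    stop("channel '", channel, "' missing from MVC reference")
  rms / mvc$rms[[channel]]
}

#' Least-squares trend of a per-cycle fatigue series
#'
#' Ordinary least squares of value on mid-time (seconds from exercise
#' onset). The initial value is the intercept at t = 0 -- extrapolated, so
#' it refers to exercise onset even when early cycles were excluded -- and
#' the normalized slope is 100 * slope / intercept in percent of the
#' initial value per second.
#'
#' @param t_mid segment mid-times, seconds from exercise onset.
#' @param value series values (normalized RMS, or IMDF in Hz).
#' @return object of class `trend_summary`: list with `initial_value`,
#'   `slope`, `normalized_slope` (\%/s; `NA` if the intercept is 0),
#'   `n_points`, `r_squared`.
#' @export
fit_trend <- function(t_mid, value) {
  ok <- is.finite(t_mid) & is.finite(value)
  t_mid <- t_mid[ok]; value <- value[ok]
  if (length(t_mid) < 5)
    stop("need at least 5 points to fit a fatigue trend (got ",
         length(t_mid), ")")
  if (diff(range(t_mid)) == 0) stop("degenerate series: all mid-times equal")
  fit <- lm(value ~ t_mid)
  b <- unname(coef(fit))
  ssr <- sum(fit$residuals^2)
  sst <- sum((value - mean(value))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  # an intercept indistinguishable from zero at the data's scale leaves
  # the normalized slope undefined
  zero_icpt <- abs(b[1]) <= 1e-10 * max(abs(value), .Machine$double.xmin)
  structure(list(
    initial_value = b[1], slope = b[2],
    normalized_slope = if (!zero_icpt) 100 * b[2] / b[1] else NA_real_,
    n_points = length(t_mid), r_squared = r2), class = "trend_summary")
}

#' Per-segment RMS and IMDF metrics for one trial
#'
#' Band-pass filters each channel, then computes per retained segment the
#' RMS (raw and MVC-normalized) and the segment IMDF.
#'
#' @param rec cyclic `semg_recording`.
#' @param segments output of [segment_cycles()].
#' @param mvc an `mvc_reference`.
#' @param sigma,n_times passed to [segment_imdf()].
#' @param include_excluded keep rows for excluded segments (default FALSE).
#' @return data.frame: `channel`, `level`, `side`, `cycle_index`, `phase`,
#'   `t_mid_s`, `rms_uv`, `rms_norm`, `imdf_hz`, `clip_fraction`.
#' @export
analyze_trial <- function(rec, segments, mvc, sigma = 1, n_times = 128,
                          include_excluded = FALSE) {
  validate_recording(rec)
  segs <- if (include_excluded) segments else
    segments[!segments$excluded, , drop = FALSE]
  chans <- recording_channels(rec)
  n <- nrow(rec$semg)
  out <- vector("list", nrow(chans))
  for (ci in seq_len(nrow(chans))) {
    lab <- chans$label[ci]
    xf <- bandpass_semg(rec$semg[, lab], rec$semg_rate)
    rows <- segs
    rms <- imdf <- clipf <- numeric(nrow(rows))
    for (k in seq_len(nrow(rows))) {
      i0 <- rows$start_sample[k]; i1 <- min(rows$end_sample[k], n)
      seg <- xf[(i0 + 1):i1]
      rms[k] <- segment_rms(seg)
      tr <- segment_imdf(seg, rec$semg_rate, sigma = sigma, n_times = n_times)
      imdf[k] <- tr$summary_hz
      clipf[k] <- tr$clip_fraction
    }
    out[[ci]] <- data.frame(
      channel = lab, level = chans$level[ci], side = chans$side[ci],
      cycle_index = rows$cycle_index, phase = rows$phase,
      t_mid_s = rows$t_mid_s, rms_uv = rms,
      rms_norm = rms / mvc$rms[[lab]], imdf_hz = imdf,
      clip_fraction = clipf, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fatigue trends per channel, phase and parameter
#'
#' Fits [fit_trend()] to the normalized-RMS series and to the IMDF series
#' (in Hz; only its slope is normalized) of every channel x phase.
#'
#' @param metrics output of [analyze_trial()].
#' @return data.frame: `channel`, `level`, `side`, `phase`, `parameter`
#'   (`"rms"` or `"imdf"`), `initial_value`, `slope`, `normalized_slope`,
#'   `n_points`, `r_squared`.
#' @export
trial_trends <- function(metrics) {
  rows <- list()
  for (lab in unique(metrics$channel)) {
    for (ph in unique(metrics$phase)) {
      m <- metrics[metrics$channel == lab & metrics$phase == ph, ]
      for (par in c("rms", "imdf")) {
        v <- if (par == "rms") m$rms_norm else m$imdf_hz
        tr <- fit_trend(m$t_mid_s, v)
        rows[[length(rows) + 1]] <- data.frame(
          channel = lab, level = m$level[1], side = m$side[1],
          phase = ph, parameter = par,
          initial_value = tr$initial_value, slope = tr$slope,
          normalized_slope = tr$normalized_slope,
          n_points = tr$n_points, r_squared = tr$r_squared,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Aggregate channel trends into the per-subject reporting rows
#'
#' Sides are averaged within level; the three level entries L1/L2/L5 are
#' averaged into the "all electrodes" row; the "most negative electrode"
#' row picks, independently per parameter x phase, the single channel (of
#' six) with the smallest normalized slope, reporting its initial value
#' and slope. Concentric/eccentric ratios of initial values and of
#' normalized slopes are attached per row.
#'
#' @param trends output of [trial_trends()]; all six montage channels must
#'   be present.
#' @return list of class `subject_summary` with `rows` (data.frame:
#'   `parameter`, `phase`, `row` in all/L5/L2/L1/most_negative,
#'   `initial_value`, `normalized_slope`, `channel` for the most-negative
#'   selection) and `ratios` (data.frame: `parameter`, `row`,
#'   `initial_ratio`, `slope_ratio` = concentric / eccentric).
#' @export
aggregate_subject <- function(trends) {
  expected <- default_channels()$label
  missing <- setdiff(expected, unique(trends$channel))
  if (length(missing))
    stop("missing channel trend(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (par in unique(trends$parameter)) {
    for (ph in unique(trends$phase)) {
      tr <- trends[trends$parameter == par & trends$phase == ph, ]
      lev_init <- tapply(tr$initial_value, tr$level, mean)
      lev_slope <- tapply(tr$normalized_slope, tr$level, mean)
      for (lev in c("L5", "L2", "L1"))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, phase = ph, row = lev,
          initial_value = lev_init[[lev]],
          normalized_slope = lev_slope[[lev]],
          channel = NA_character_, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, phase = ph, row = "all",
        initial_value = mean(lev_init[c("L1", "L2", "L5")]),
        normalized_slope = mean(lev_slope[c("L1", "L2", "L5")]),
        channel = NA_character_, stringsAsFactors = FALSE)
      worst <- tr[which.min(tr$normalized_slope), ]
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, phase = ph, row = "most_negative",
        initial_value = worst$initial_value,
        normalized_slope = worst$normalized_slope,
        channel = worst$channel, stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  ratios <- list()
  for (par in unique(rows$parameter)) {
    for (rw in unique(rows$row)) {
      co <- rows[rows$parameter == par & rows$row == rw &
                   rows$phase == "concentric", ]
      ec <- rows[rows$parameter == par & rows$row == rw &
                   rows$phase == "eccentric", ]
      if (!nrow(co) || !nrow(ec)) next
      ratios[[length(ratios) + 1]] <- data.frame(
        parameter = par, row = rw,
        initial_ratio = conc_ecc_ratio(co$initial_value, ec$initial_value),
        slope_ratio = if (ec$normalized_slope != 0)
          co$normalized_slope / ec$normalized_slope else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ratios <- do.call(rbind, ratios)
  rownames(ratios) <- NULL
  structure(list(rows = rows, ratios = ratios), class = "subject_summary")
}

#' Concentric / eccentric ratio
#'
#' @param conc,ecc values for the concentric and eccentric phase.
#' @return conc / ecc; errors when `ecc` is 0.
#' @export
conc_ecc_ratio <- function(conc, ecc) {
  if (any(ecc == 0)) stop("eccentric value is 0: ratio undefined")
  conc / ecc
}
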