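# Trial container on disk:
#   <trial_dir>/semg.csv   t_s + one column per channel label
#   <trial_dir>/accel.csv  t_s, acc_z_g
#   <trial_dir>/meta.json  subject_id, kind, rates, optional age/sex
# Doubles are written as %.17g so a write -> read round trip is bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

# Forward-backward filtering with edge-transient control: the straight
# line through the endpoints is removed (so the padded signal starts and
# ends at zero), the residual is extended by odd reflection, filtered
# forward-backward, trimmed, and the line restored for low-pass filters
# (a line is DC plus a slow ramp, which a low-pass passes unchanged at
# zero phase) or dropped for high-pass filters (which remove it anyway).
zp_filtfilt <- function(bf, x, pad, restore_trend) {
  n <- length(x)
  line <- x[1] + (x[n] - x[1]) * (0:(n - 1)) / (n - 1)
  r <- x - line
  p <- min(n - 1, pad)
  xe <- if (p > 0)
    c(2 * r[1] - r[(p + 1):2], r, 2 * r[n] - r[(n - 1):(n - p)])
  else r
  y <- signal::filtfilt(bf, xe)[(p + 1):(p + n)]
  if (restore_trend) y + line else y
}

write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  data.table::fwrite(out, path, quote = FALSE)
}

#' Write a Recording to a trial directory
#'
#' @param rec a `semg_recording`.
#' @param path directory to create/populate with `semg.csv`, `accel.csv`
#'   and `meta.json`.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(rec$semg)
  semg_df <- data.frame(t_s = (seq_len(n) - 1) / rec$semg_rate)
  for (lab in colnames(rec$semg)) semg_df[[lab]] <- rec$semg[, lab]
  write_num_csv(semg_df, file.path(path, "semg.csv"))
  na <- length(rec$accel_z)
  accel_df <- data.frame(t_s = (seq_len(na) - 1) / rec$accel_rate,
                         acc_z_g = rec$accel_z)
  write_num_csv(accel_df, file.path(path, "accel.csv"))
  meta <- rec$meta
  meta$semg_rate <- rec$semg_rate
  meta$accel_rate <- rec$accel_rate
  meta$channels <- colnames(rec$semg)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a Recording from a trial directory
#'
#' Validates the container against the schema (channel labels declared in
#' the sidecar must match `semg.csv` columns, rates must be positive) and
#' errors naming the offending field otherwise.
#'
#' @param path trial directory written by [write_recording()].
#' @return a `semg_recording`.
#' @export
read_recording <- function(path) {
  need <- c("semg.csv", "accel.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("trial container at '", path, "' is missing: ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  for (field in c("semg_rate", "accel_rate", "channels", "subject_id", "kind"))
    if (is.null(meta[[field]]))
      stop("meta.json is missing field '", field, "'")
  semg_df <- data.table::fread(file.path(path, "semg.csv"), data.table = FALSE)
  if (!"t_s" %in% names(semg_df)) stop("semg.csv is missing column 't_s'")
  chan <- as.character(meta$channels)
  absent <- setdiff(chan, names(semg_df))
  if (length(absent))
    stop("semg.csv is missing declared channel(s): ",
         paste(absent, collapse = ", "))
  semg <- as.matrix(semg_df[, chan, drop = FALSE])
  accel_df <- data.table::fread(file.path(path, "accel.csv"), data.table = FALSE)
  if (!"acc_z_g" %in% names(accel_df))
    stop("accel.csv is missing column 'acc_z_g'")
  meta_list <- as.list(meta)
  meta_list$semg_rate <- NULL; meta_list$accel_rate <- NULL
  meta_list$channels <- NULL
  new_recording(semg = semg, semg_rate = as.numeric(meta$semg_rate),
                accel_z = accel_df$acc_z_g,
                accel_rate = as.numeric(meta$accel_rate),
                meta = meta_list)
}

#' Zero-phase 20--500 Hz band-pass pre-filter for SEMG
#'
#' Applies a 4th-order 20 Hz high-pass and a 4th-order 500 Hz low-pass
#' Butterworth filter, each forward-backward (zero phase), as the standard
#' SEMG conditioning chain. Output length equals input length.
#'
#' @param x numeric vector of SEMG samples (microvolts).
#' @param rate sampling rate in Hz; must exceed 1000 Hz so the 500 Hz
#'   cut-off lies below Nyquist.
#' @param low,high band edges in Hz.
#' @param order Butterworth order of each half of the cascade.
#' @return filtered samples, same length as `x`.
#' @export
bandpass_semg <- function(x, rate, low = 20, high = 500, order = 4) {
  if (rate <= 2 * high)
    stop("sampling rate ", rate, " Hz too low: ", high,
         " Hz cut-off at or above Nyquist")
  hp <- signal::butter(order, low / (rate / 2), type = "high")
  lp <- signal::butter(order, high / (rate / 2), type = "low")
  pad <- round(3 * rate / low)
  y <- zp_filtfilt(hp, x, pad, restore_trend = FALSE)
  zp_filtfilt(lp, y, pad, restore_trend = TRUE)
}

#' RMS reference from an 80% MVC recording
#'
#' Per-channel RMS amplitude over the window from 2 s to 5 s (half-open,
#' exactly 3 s) of the sustained 80\% maximum-voluntary-contraction
#' recording, after band-pass pre-filtering. Used to normalize RMS values
#' from the cyclic exercise.
#'
#' @param rec a `semg_recording` of kind `"mvc80"` (or any recording at
#'   least 5 s long).
#' @param window numeric length-2, window in seconds (half-open).
#' @param filter logical; apply [bandpass_semg()] first (default TRUE).
#' @return object of class `mvc_reference`: list with `rms` (named numeric,
#'   microvolts) and `window` (seconds).
#' @export
mvc_reference <- function(rec, window = c(2, 5), filter = TRUE) {
  validate_recording(rec)
  dur <- nrow(rec$semg) / rec$semg_rate
  if (dur < window[2])
    stop("MVC recording is ", round(dur, 2), " s; need at least ",
         window[2], " s")
  i0 <- floor(window[1] * rec$semg_rate) + 1L
  i1 <- floor(window[2] * rec$semg_rate)        # half-open [2, 5)
  # filter the extracted window only, so samples outside it cannot leak in
  rms <- vapply(colnames(rec$semg), function(lab) {
    x <- rec$semg[i0:i1, lab]
    if (filter) x <- bandpass_semg(x, rec$semg_rate)
    sqrt(mean(x^2))
  }, numeric(1))
  if (any(rms <= 0)) stop("MVC reference RMS must be positive for all channels")
  structure(list(rms = rms, window = window), class = "mvc_reference")
}
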