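#' SEMG electrode montage levels and sides
#'
#' The standard montage records the back extensors bilaterally at three
#' spinal levels: multifidus at L5, longissimus dorsi at L2 and iliocostalis
#' lumborum at L1.
#' @keywords internal
#' @name montage
NULL

.levels <- c("L1", "L2", "L5")
.sides <- c("left", "right")

#' Default six-channel montage
#'
#' @return data.frame with columns `level`, `side`, `label` (e.g. "L5_left").
#' @export
default_channels <- function() {
  ch <- expand.grid(side = .sides, level = .levels,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ch <- ch[, c("level", "side")]
  ch$label <- paste(ch$level, ch$side, sep = "_")
  ch[order(ch$label), , drop = FALSE]
}

#' Construct a Recording
#'
#' A Recording bundles the synchronized SEMG channels (microvolts), the
#' lever-arm accelerometer z-axis trace (units of g) and trial metadata.
#'
#' @param semg numeric matrix, samples x channels; column names are channel
#'   labels of the form `<level>_<side>`.
#' @param semg_rate SEMG sampling rate in Hz.
#' @param accel_z numeric vector, accelerometer z-axis in g.
#' @param accel_rate accelerometer sampling rate in Hz.
#' @param meta list with at least `subject_id` and `kind` (one of
#'   `"mvc80"`, `"cyclic"`); optionally `age` (years) and `sex`.
#' @return object of class `semg_recording`.
#' @export
new_recording <- function(semg, semg_rate, accel_z, accel_rate, meta) {
  rec <- structure(
    list(semg = semg, semg_rate = semg_rate,
         accel_z = accel_z, accel_rate = accel_rate, meta = meta),
    class = "semg_recording")
  validate_recording(rec)
}

#' Validate a Recording's structural invariants
#'
#' Checks shared channel length/rate, unique labels drawn from the L1/L2/L5
#' by left/right montage, positive rates and required metadata fields.
#'
#' @param rec a `semg_recording`.
#' @return the validated recording, invisibly unchanged.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$semg) || !is.numeric(rec$semg))
    stop("recording field 'semg' must be a numeric matrix (samples x channels)")
  labels <- colnames(rec$semg)
  if (is.null(labels) || anyDuplicated(labels))
    stop("recording field 'semg' must have unique channel labels as column names")
  parts <- strsplit(labels, "_", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) == 2 && p[1] %in% .levels && p[2] %in% .sides
  }, logical(1))
  if (!all(ok))
    stop("invalid channel label(s): ", paste(labels[!ok], collapse = ", "),
         " (expected <level>_<side>, level in {L1,L2,L5}, side in {left,right})")
  if (!is.numeric(rec$semg_rate) || length(rec$semg_rate) != 1 || rec$semg_rate <= 0)
    stop("recording field 'semg_rate' must be a positive scalar")
  if (is.null(rec$accel_z) || !is.numeric(rec$accel_z))
    stop("recording field 'accel_z' is missing or non-numeric")
  if (!is.numeric(rec$accel_rate) || length(rec$accel_rate) != 1 || rec$accel_rate <= 0)
    stop("recording field 'accel_rate' must be a positive scalar")
  meta <- rec$meta
  if (is.null(meta$subject_id))
    stop("recording field 'meta.subject_id' is missing")
  if (is.null(meta$kind) || !meta$kind %in% c("mvc80", "cyclic"))
    stop("recording field 'meta.kind' must be one of 'mvc80', 'cyclic'")
  invisible(rec)
}

#' Channel table of a recording
#' @param rec a `semg_recording`.
#' @return data.frame with `level`, `side`, `label` in column order of `semg`.
#' @export
recording_channels <- function(rec) {
  labels <- colnames(rec$semg)
  parts <- do.call(rbind, strsplit(labels, "_", fixed = TRUE))
  data.frame(level = parts[, 1], side = parts[, 2], label = labels,
             stringsAsFactors = FALSE)
}

#' @export
print.semg_recording <- function(x, ...) {
  dur <- nrow(x$semg) / x$semg_rate
  cat(sprintf("<semg_recording> subject %s, kind %s\n",
              x$meta$subject_id, x$meta$kind))
  cat(sprintf("  %d SEMG channels @ %g Hz, %.1f s (%s)\n",
              ncol(x$semg), x$semg_rate, dur,
              paste(colnames(x$semg), collapse = ", ")))
  cat(sprintf("  accelerometer: %d samples @ %g Hz\n",
              length(x$accel_z), x$accel_rate))
  invisible(x)
}
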