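#' @keywords internal
"_PACKAGE"

#' Construct a single-limb marker recording
#'
#' A recording holds the 3D position time series of the four upper-limb
#' markers (FN index fingernail, LEP lateral epicondyle, MPH mid-humerus,
#' ACR acromion) for one limb performing one activity, together with the
#' metadata the downstream statistics need (class label, side, participant).
#'
#' @param markers named list over `FN`, `LEP`, `MPH`, `ACR`; each element a
#'   numeric matrix with columns `x`, `y`, `z` (one row per frame, all four
#'   matrices the same number of rows, at least 2).
#' @param sampling_rate_hz sampling rate in Hz (positive).
#' @param recording_id,participant_id identifier strings.
#' @param class_label one of `"G0"` (non-affected post-stroke limb),
#'   `"G1"` (affected limb), `"G2"` (healthy-control limb).
#' @param side `"left"` or `"right"`.
#' @param activity one of `"large_cylinder"`, `"small_cylinder"`,
#'   `"drinking"`.
#' @return an object of class `limb_recording`.
#' @export
limb_recording <- function(markers, sampling_rate_hz,
                           recording_id = "rec", participant_id = "p",
                           class_label = "G0", side = "left",
                           activity = "large_cylinder") {
  if (!is.list(markers) || !setequal(names(markers), MARKERS)) {
    stop("`markers` must be a named list over FN, LEP, MPH, ACR", call. = FALSE)
  }
  markers <- lapply(markers[MARKERS], function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker needs 3 coordinate columns", call. = FALSE)
    colnames(m) <- AXES
    storage.mode(m) <- "double"
    m
  })
  n <- vapply(markers, nrow, integer(1))
  if (length(unique(n)) != 1L || n[1] < 2L) {
    stop("all 12 coordinate series must have equal length >= 2", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  class_label <- match.arg(class_label, CLASS_LABELS)
  side <- match.arg(side, SIDES)
  activity <- match.arg(activity, ACTIVITIES)
  structure(
    list(recording_id = as.character(recording_id),
         participant_id = as.character(participant_id),
         class_label = class_label, side = side, activity = activity,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         markers = markers),
    class = "limb_recording"
  )
}

#' @export
print.limb_recording <- function(x, ...) {
  cat(sprintf(
    "<limb_recording %s> participant %s, class %s, %s side, %s\n  %d frames @ %g Hz, markers: %s\n",
    x$recording_id, x$participant_id, x$class_label, x$side, x$activity,
    n_frames(x), x$sampling_rate_hz, paste(MARKERS, collapse = " ")))
  invisible(x)
}

#' Number of frames in a recording
#' @param recording a `limb_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(recording) nrow(recording$markers[[1]])
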