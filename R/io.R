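# Text interchange for recordings (TRC and wide CSV) and cohort manifests.
# TRC follows the de-facto motion-capture dialect: tab-separated, a
# PathFileType line, a DataRate header pair, a marker-name row with X/Y/Z
# triples, and 1-based frame numbers (converted to 0-based internally).

CSV_COLUMNS <- c("Frame", "Time",
                 as.vector(t(outer(MARKERS, AXES, paste, sep = "_"))))

#' Write a recording to disk
#'
#' @param recording a [limb_recording()].
#' @param path output file path.
#' @param format `"trc"` or `"csv"`. The CSV layout is `Frame, Time`, then
#'   `FN,LEP,MPH,ACR` x `x,y,z` columns, preceded by `#key=value` metadata
#'   lines (sampling rate and labels). Positions are written with 12
#'   significant digits so a read/write round trip is lossless well beyond
#'   capture precision.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path, format = c("trc", "csv")) {
  format <- match.arg(format)
  if (!inherits(recording, "limb_recording")) {
    stop("not a limb_recording", call. = FALSE)
  }
  n <- n_frames(recording)
  rate <- recording$sampling_rate_hz
  tm <- (seq_len(n) - 1L) / rate
  coord <- do.call(cbind, lapply(recording$markers, identity))
  num <- function(v) formatC(v, digits = 12, format = "g")
  if (format == "trc") {
    hdr <- c(
      paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
      paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
      paste(rate, rate, n, length(MARKERS), "m", rate, 1, n, sep = "\t"),
      paste(c("Frame#", "Time",
              as.vector(rbind(MARKERS, "", ""))), collapse = "\t"),
      paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(MARKERS)),
                             rep(seq_along(MARKERS), each = 3))),
            collapse = "\t"))
    body <- paste(seq_len(n), num(tm),
                  apply(coord, 1, function(r) paste(num(r), collapse = "\t")),
                  sep = "\t")
    writeLines(c(hdr, body), path)
  } else {
    meta <- c(
      sprintf("#sampling_rate_hz=%s", num(rate)),
      sprintf("#recording_id=%s", recording$recording_id),
      sprintf("#participant_id=%s", recording$participant_id),
      sprintf("#class_label=%s", recording$class_label),
      sprintf("#side=%s", recording$side),
      sprintf("#activity=%s", recording$activity))
    body <- paste(seq_len(n) - 1L, num(tm),
                  apply(coord, 1, function(r) paste(num(r), collapse = ",")),
                  sep = ",")
    writeLines(c(meta, paste(CSV_COLUMNS, collapse = ","), body), path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path file path.
#' @param format `"trc"` or `"csv"` (see [write_recording()] for layouts).
#' @param recording_id,participant_id,class_label,side,activity metadata
#'   overrides; for TRC (which carries no labels) these default to
#'   placeholders and are normally supplied from the cohort manifest. For CSV
#'   they default to the file's `#key=value` metadata lines.
#' @return a [limb_recording()].
#' @export
read_recording <- function(path, format = c("trc", "csv"),
                           recording_id = NULL, participant_id = NULL,
                           class_label = NULL, side = NULL, activity = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "trc") {
    lines <- readLines(path)
    if (length(lines) < 6L || !startsWith(lines[1], "PathFileType")) {
      stop("not a TRC file: ", path, call. = FALSE)
    }
    hdr_names <- strsplit(lines[2], "\t")[[1]]
    hdr_vals <- strsplit(lines[3], "\t")[[1]]
    rate <- as.numeric(hdr_vals[match("DataRate", hdr_names)])
    marker_row <- strsplit(lines[4], "\t")[[1]]
    marker_names <- marker_row[-(1:2)]
    marker_names <- marker_names[marker_names != ""]
    missing <- setdiff(MARKERS, marker_names)
    if (length(missing)) {
      stop("TRC file missing marker(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    dat <- utils::read.delim(text = lines[-(1:5)], header = FALSE)
    if (ncol(dat) != 2 + 3 * length(marker_names)) {
      stop("ragged TRC data columns in ", path, call. = FALSE)
    }
    coord <- as.matrix(dat[, -(1:2)])
    markers <- stats::setNames(lapply(MARKERS, function(m) {
      j <- 3 * (match(m, marker_names) - 1)
      coord[, j + 1:3, drop = FALSE]
    }), MARKERS)
  } else {
    lines <- readLines(path)
    meta_lines <- grep("^#", lines, value = TRUE)
    meta <- stats::setNames(
      sub("^#[^=]*=", "", meta_lines),
      sub("^#([^=]*)=.*$", "\\1", meta_lines))
    dat <- utils::read.csv(text = lines[!startsWith(lines, "#")])
    missing <- setdiff(CSV_COLUMNS, names(dat))
    if (length(missing)) {
      stop("CSV missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    rate <- as.numeric(meta[["sampling_rate_hz"]])
    markers <- stats::setNames(lapply(MARKERS, function(m) {
      as.matrix(dat[, paste(m, AXES, sep = "_")])
    }), MARKERS)
    if (is.null(recording_id)) recording_id <- meta[["recording_id"]]
    if (is.null(participant_id)) participant_id <- meta[["participant_id"]]
    if (is.null(class_label)) class_label <- meta[["class_label"]]
    if (is.null(side)) side <- meta[["side"]]
    if (is.null(activity)) activity <- meta[["activity"]]
  }
  limb_recording(markers, sampling_rate_hz = rate,
                 recording_id = recording_id %||% "rec",
                 participant_id = participant_id %||% "p",
                 class_label = class_label %||% "G0",
                 side = side %||% "left",
                 activity = activity %||% "large_cylinder")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

MANIFEST_COLUMNS <- c("recording_id", "path", "class_label",
                      "participant_id", "side", "activity")

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with columns `recording_id, path, class_label,
#' participant_id, side, activity`; recording ids must be unique and class
#' labels drawn from G0/G1/G2.
#'
#' @param manifest a data.frame with the manifest columns (a missing `path`
#'   column is added as `NA` on write).
#' @param path CSV file path.
#' @return `read_manifest` returns the validated data.frame;
#'   `write_manifest` returns the path invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  if (!("path" %in% names(manifest))) manifest$path <- NA_character_
  manifest <- validate_manifest(manifest)
  utils::write.csv(manifest[, MANIFEST_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  if (!("path" %in% names(m))) m$path <- NA_character_
  missing <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing)) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$recording_id)) {
    stop("duplicate recording_id in manifest", call. = FALSE)
  }
  bad <- setdiff(unique(m$class_label), CLASS_LABELS)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m[, MANIFEST_COLUMNS]
}
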