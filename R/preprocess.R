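# Preprocessing: side unification, lift-phase cropping, derivation of the
# 60 kinematic series per recording, and per-series min-max normalisation.

#' Unify movement side by sagittal-plane reflection
#'
#' Right-limb recordings are mirrored through the sagittal (yz) plane by
#' negating every marker's x coordinate, so both limbs share one coordinate
#' convention; left-limb recordings pass through unchanged. Applied before
#' derivative computation so velocity and acceleration signs stay consistent.
#'
#' @param recording a [limb_recording()].
#' @return the recording, reflected if it was a right limb. The `side` field
#'   is kept (it records provenance); the returned object gains an attribute
#'   `side_unified = TRUE`.
#' @export
reflect_to_common_side <- function(recording) {
  if (!inherits(recording, "limb_recording")) {
    stop("not a limb_recording", call. = FALSE)
  }
  if (recording$side == "right") {
    recording$markers <- lapply(recording$markers, function(m) {
      m[, "x"] <- -m[, "x"]
      m
    })
  }
  attr(recording, "side_unified") <- TRUE
  recording
}

#' Crop a recording to the lift-lower phase
#'
#' The activity window is detected on the vertical (z) series of the distal
#' FN marker: the threshold is `threshold_frac` of that series' full range,
#' and the window runs from the first to the last sample whose FNz value
#' exceeds the starting value plus the threshold. All twelve coordinate
#' series are cropped to that window.
#'
#' @param recording a [limb_recording()].
#' @param threshold_frac fraction of the FNz range used as threshold
#'   (default 0.10).
#' @return list of class `crop_result` with `start_index`, `end_index`
#'   (1-based, inclusive), `threshold_value`, and `cropped` (the cropped
#'   [limb_recording()]).
#' @export
crop_to_lift <- function(recording, threshold_frac = 0.10) {
  if (!inherits(recording, "limb_recording")) {
    stop("not a limb_recording", call. = FALSE)
  }
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  }
  fnz <- recording$markers$FN[, "z"]
  rng <- max(fnz) - min(fnz)
  if (rng <= 0) {
    stop("degenerate input: FN z-series is constant (zero range)",
         call. = FALSE)
  }
  theta <- threshold_frac * rng
  above <- which(fnz > fnz[1] + theta)
  if (!length(above)) {
    stop("no movement detected: no FNz sample exceeds start value + threshold",
         call. = FALSE)
  }
  start <- above[1]
  end <- above[length(above)]
  if (end - start + 1L < 2L) {
    stop("no movement detected: activity window shorter than 2 samples",
         call. = FALSE)
  }
  cropped <- recording
  cropped$markers <- lapply(recording$markers,
                            function(m) m[start:end, , drop = FALSE])
  structure(list(start_index = start, end_index = end,
                 threshold_value = theta, cropped = cropped),
            class = "crop_result")
}

SERIES_PER_MARKER <- c("x", "y", "z", "dx", "dy", "dz", "D",
                       "vx", "vy", "vz", "V", "ax", "ay", "az", "A")

#' Names of the 60 derived kinematic series
#'
#' Per marker M in FN, LEP, MPH, ACR: trajectory `Mx,My,Mz`; displacement
#' from the first cropped sample `Mdx,Mdy,Mdz` and its module `MD`; velocity
#' `Mvx,Mvy,Mvz` and speed `MV`; acceleration `Max,May,Maz` and its module
#' `MA` (15 series per marker).
#'
#' @return character vector of the 60 series names in canonical order.
#' @export
derived_series_names <- function() {
  as.vector(t(outer(MARKERS, SERIES_PER_MARKER, paste0)))
}

# central first difference, one-sided at the two ends
deriv1 <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) * rate / 2
  }
  d
}

# central second difference, replicated at the two ends
deriv2 <- function(x, rate) {
  n <- length(x)
  a <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    a[i] <- (x[i + 1] - 2 * x[i] + x[i - 1]) * rate^2
    a[1] <- a[2]
    a[n] <- a[n - 1]
  }
  a
}

#' Derive the 60 kinematic time series from a cropped recording
#'
#' Trajectory series are the cropped coordinates. Displacement is measured
#' from the first cropped sample (`Mdx[i] = Mx[i] - Mx[1]`), so the
#' displacement module is a distance-from-start signal and starts at 0.
#' Velocity uses central first differences scaled by the sampling rate
#' (one-sided at the ends); acceleration uses central second differences
#' scaled by rate squared (end values replicated from their neighbours).
#' Each module series is the per-sample Euclidean norm of its 3-vector.
#'
#' @param recording a cropped [limb_recording()] with at least 3 frames.
#' @return named list of 60 equal-length numeric vectors
#'   (class `derived_series_set`).
#' @export
derive_series <- function(recording) {
  if (!inherits(recording, "limb_recording")) {
    stop("not a limb_recording", call. = FALSE)
  }
  if (n_frames(recording) < 3L) {
    stop("cropped recording too short for second differences (need >= 3 frames)",
         call. = FALSE)
  }
  rate <- recording$sampling_rate_hz
  out <- list()
  for (m in MARKERS) {
    pos <- recording$markers[[m]]
    disp <- sweep(pos, 2, pos[1, ])
    vel <- apply(pos, 2, deriv1, rate = rate)
    acc <- apply(pos, 2, deriv2, rate = rate)
    for (k in seq_along(AXES)) {
      ax <- AXES[k]
      out[[paste0(m, ax)]] <- pos[, k]
      out[[paste0(m, "d", ax)]] <- disp[, k]
      out[[paste0(m, "v", ax)]] <- vel[, k]
      out[[paste0(m, "a", ax)]] <- acc[, k]
    }
    out[[paste0(m, "D")]] <- sqrt(rowSums(disp^2))
    out[[paste0(m, "V")]] <- sqrt(rowSums(vel^2))
    out[[paste0(m, "A")]] <- sqrt(rowSums(acc^2))
  }
  structure(out[derived_series_names()], class = "derived_series_set")
}

#' Min-max normalise a series to [0, 1]
#'
#' Constant series map to all zeros and carry a `constant = TRUE` attribute
#' so downstream stages can flag them.
#'
#' @param x non-empty numeric vector.
#' @return normalised numeric vector with min 0 and max 1 (or all zeros for
#'   constant input).
#' @export
normalize_minmax <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(structure(rep(0, length(x)), constant = TRUE))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Smooth marker trajectories
#'
#' Optional Savitzky-Golay smoothing (cubic, 9-sample window at 100 Hz,
#' passband roughly up to 12-14 Hz) of each coordinate series, applied
#' before differentiation. Double-differencing at 100 Hz amplifies white
#' sensor noise by four orders of magnitude, so unsmoothed acceleration
#' series are dominated by the sensor-noise floor; smoothing recovers the
#' band-limited movement content in the derivative domains.
#'
#' @param recording a [limb_recording()].
#' @param window odd window length in samples (default 9).
#' @param order polynomial order (default 3).
#' @return the recording with smoothed coordinates.
#' @export
smooth_recording <- function(recording, window = 9L, order = 3L) {
  if (!inherits(recording, "limb_recording")) {
    stop("not a limb_recording", call. = FALSE)
  }
  recording$markers <- lapply(recording$markers, function(m) {
    apply(m, 2, signal::sgolayfilt, p = order, n = window)
  })
  recording
}

#' Preprocess one recording end to end
#'
#' Runs reflect -> (optional smooth) -> crop -> derive -> normalise and
#' returns the 60 normalised series.
#'
#' @param recording a [limb_recording()].
#' @param threshold_frac crop threshold fraction (default 0.10).
#' @param smoothing apply [smooth_recording()] before cropping and
#'   differentiation (default `FALSE`).
#' @return a `derived_series_set` of min-max normalised series; the crop
#'   result is attached as attribute `crop`.
#' @export
preprocess_recording <- function(recording, threshold_frac = 0.10,
                                 smoothing = FALSE) {
  rec <- reflect_to_common_side(recording)
  if (isTRUE(smoothing)) rec <- smooth_recording(rec)
  cr <- crop_to_lift(rec, threshold_frac)
  ds <- derive_series(cr$cropped)
  out <- lapply(ds, normalize_minmax)
  structure(out, class = "derived_series_set",
            crop = cr[c("start_index", "end_index", "threshold_value")])
}
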