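# Minimal-jerk cohort simulator: reach-lift-return recordings with the class
# structure and amplitude gradation of an upper-limb lifting protocol.

#' Minimal-jerk position profile
#'
#' Quintic point-to-point profile minimising integrated squared jerk,
#' x(t) = x0 + (xf - x0) (10 tau^3 - 15 tau^4 + 6 tau^5) with tau = t/T.
#' It starts and ends at rest and has the bell-shaped velocity profile
#' characteristic of unconstrained reaching movements.
#'
#' @param x0,xf start and end positions.
#' @param duration_s movement duration T in seconds (positive).
#' @param sampling_rate_hz sampling rate in Hz (positive).
#' @return numeric vector of positions sampled at t = 0, 1/rate, ..., with the
#'   final sample at t = T (the grid always includes both endpoints).
#' @export
minimal_jerk_profile <- function(x0, xf, duration_s, sampling_rate_hz) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  n <- max(2L, as.integer(round(duration_s * sampling_rate_hz)) + 1L)
  tau <- seq(0, 1, length.out = n)
  x0 + (xf - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Class-effect descriptor for the cohort simulator
#'
#' Encodes one way a class's recordings differ from the baseline movement, on
#' one marker and axis: `amplitude_scale` multiplies the movement amplitude by
#' `magnitude`; `submovement_count` superimposes `magnitude` extra small
#' minimal-jerk pulses (corrective submovements); `jerk_noise_sd` adds
#' tremor-like oscillatory roughness in the physiological tremor band — a
#' sinusoidal positional oscillation with per-recording random frequency
#' (8-12 Hz) and phase, of standard deviation `magnitude` (same units as
#' coordinates). Because differentiation weights a band-limited oscillation
#' by its frequency (velocity) and frequency squared (acceleration), this
#' effect leaves the trajectory nearly untouched and predominantly alters
#' acceleration-domain statistics.
#'
#' @param target_class class receiving the effect (`"G0"`, `"G1"`, `"G2"`).
#' @param marker one of `"FN"`, `"LEP"`, `"MPH"`, `"ACR"`.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param effect_kind `"amplitude_scale"`, `"submovement_count"` or
#'   `"jerk_noise_sd"`.
#' @param magnitude nonnegative effect size (scale factor, pulse count, or
#'   noise standard deviation respectively).
#' @return a `class_effect` list.
#' @export
class_effect <- function(target_class, marker, axis, effect_kind, magnitude) {
  target_class <- match.arg(target_class, CLASS_LABELS)
  marker <- match.arg(marker, MARKERS)
  axis <- match.arg(axis, AXES)
  effect_kind <- match.arg(effect_kind,
                           c("amplitude_scale", "submovement_count", "jerk_noise_sd"))
  if (!is.numeric(magnitude) || magnitude < 0) {
    stop("magnitude must be >= 0", call. = FALSE)
  }
  if (effect_kind == "amplitude_scale" && magnitude == 0) {
    stop("amplitude_scale effect must keep amplitudes positive", call. = FALSE)
  }
  structure(list(target_class = target_class, marker = marker, axis = axis,
                 effect_kind = effect_kind, magnitude = magnitude),
            class = "class_effect")
}

#' Simulation configuration for a reach-lift cohort
#'
#' Defaults emulate the lifting protocol the analysis was designed for: a
#' 100 Hz optical capture of a seated reach-lift-return, with the distal
#' fingernail marker travelling farthest (about 0.5 m vertically when lifting
#' as high as possible) and excursion tapering proximally along the
#' FN > LEP > MPH > ACR chain. Rest padding before and after the lift gives
#' the cropping stage something to remove. Per-participant movement scale
#' varies log-normally (sd 0.1) so recordings within a class are exchangeable
#' but not identical.
#'
#' @param n_stroke number of post-stroke participants (each contributes both
#'   a non-affected G0 and an affected G1 limb).
#' @param n_control number of healthy-control participants (both limbs G2).
#' @param recordings_per_limb recordings of each limb per participant.
#' @param sampling_rate_hz capture rate in Hz.
#' @param movement_duration_s total lift-plus-lower duration in seconds.
#' @param marker_amplitude_scale named numeric in (0, 1] per marker, distal
#'   largest.
#' @param base_amplitude_m vertical excursion of a scale-1 marker in metres.
#' @param rest_padding_s still time before and after the movement in seconds.
#' @param noise_sd additive i.i.d. Gaussian sensor noise per sample and
#'   axis, in metres (default 50 micrometres, the residual jitter scale of
#'   filtered optical marker capture).
#' @param participant_sd standard deviation of the per-participant log-normal
#'   amplitude factor (0 disables inter-participant variability).
#' @param shape_variability relative amplitude of per-recording low-frequency
#'   (0.3-1.5 Hz) motor variability superimposed on the movement, as a
#'   fraction of each coordinate's excursion (default 0.05; 0 disables it).
#'   Repeated reaches are never kinematically identical; without this term
#'   every normalised trajectory in a class would be the same curve plus
#'   sensor noise, which no capture system produces.
#' @param class_effects list of [class_effect()] objects.
#' @param activity activity label stamped on the recordings.
#' @param seed integer master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_stroke = 35L, n_control = 19L,
                              recordings_per_limb = 3L,
                              sampling_rate_hz = 100,
                              movement_duration_s = 2.5,
                              marker_amplitude_scale = c(FN = 1, LEP = 0.7,
                                                         MPH = 0.4, ACR = 0.15),
                              base_amplitude_m = 0.5,
                              rest_padding_s = 0.5,
                              noise_sd = 5e-5,
                              participant_sd = 0.1,
                              shape_variability = 0.05,
                              class_effects = list(),
                              activity = "large_cylinder",
                              seed = 1L) {
  stopifnot(n_stroke >= 0, n_control >= 0, recordings_per_limb >= 1)
  if (movement_duration_s <= 0 || sampling_rate_hz <= 0) {
    stop("duration and sampling rate must be positive", call. = FALSE)
  }
  if (rest_padding_s < 0) stop("rest_padding_s must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (shape_variability < 0) {
    stop("shape_variability must be >= 0", call. = FALSE)
  }
  if (!setequal(names(marker_amplitude_scale), MARKERS) ||
      any(marker_amplitude_scale <= 0)) {
    stop("marker_amplitude_scale needs positive entries for FN, LEP, MPH, ACR",
         call. = FALSE)
  }
  if (!all(vapply(class_effects, inherits, logical(1), "class_effect"))) {
    stop("class_effects must be a list of class_effect objects", call. = FALSE)
  }
  structure(list(
    n_stroke = as.integer(n_stroke), n_control = as.integer(n_control),
    recordings_per_limb = as.integer(recordings_per_limb),
    sampling_rate_hz = sampling_rate_hz,
    movement_duration_s = movement_duration_s,
    marker_amplitude_scale = marker_amplitude_scale[MARKERS],
    base_amplitude_m = base_amplitude_m,
    rest_padding_s = rest_padding_s, noise_sd = noise_sd,
    participant_sd = participant_sd,
    shape_variability = shape_variability,
    class_effects = class_effects,
    activity = match.arg(activity, ACTIVITIES),
    seed = as.integer(seed)), class = "simulation_config")
}

# Deterministic 31-bit hash of a string, for fanning the master seed out to
# per-recording seeds so subsetting a cohort never shifts other recordings.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Relative axis amplitudes of the lift: vertical dominant, forward reach
# moderate, transverse small.
AXIS_WEIGHTS <- c(x = 0.1, y = 0.4, z = 1.0)

#' Simulate one reach-lift-return recording
#'
#' Each marker coordinate follows a minimal-jerk rise to its peak excursion
#' followed by a minimal-jerk return, flanked by still rest padding; the z
#' axis dominates and the FN marker travels farthest. All class effects in
#' the configuration whose `target_class` matches are applied. Output is a
#' deterministic function of (config, class, participant, side, seed).
#'
#' @param config a [simulation_config()].
#' @param class_label class of this limb (`"G0"`, `"G1"`, `"G2"`).
#' @param participant_id,side,recording_id metadata for the recording.
#' @param seed integer seed for this recording's noise.
#' @return a [limb_recording()].
#' @export
simulate_recording <- function(config, class_label, participant_id,
                               side = "left", seed = config$seed,
                               recording_id = NULL) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  if (!is.character(class_label) || !(class_label %in% CLASS_LABELS)) {
    stop("unknown class label: ", class_label, call. = FALSE)
  }
  side <- match.arg(side, SIDES)
  if (is.null(recording_id)) {
    recording_id <- paste(participant_id, side, class_label, sep = "_")
  }
  rate <- config$sampling_rate_hz
  n_pad <- as.integer(round(config$rest_padding_s * rate))
  half <- config$movement_duration_s / 2

  old <- .Random.seed_exists()
  set.seed(seed %% 2147483647L)

  # participant-level movement scale, seeded from the participant id so it is
  # stable across that participant's recordings
  p_scale <- 1
  if (config$participant_sd > 0) {
    ps <- (stable_hash(as.character(participant_id)) + config$seed) %% 2147483647L
    p_scale <- local({
      set.seed(ps)
      exp(stats::rnorm(1, 0, config$participant_sd))
    })
    set.seed(seed %% 2147483647L)  # restore recording-level stream
  }

  effects <- Filter(function(e) e$target_class == class_label,
                    config$class_effects)

  # per-recording low-frequency motor variability: one 3-component random
  # oscillation per axis, shared across markers (the whole arm deviates
  # together) and scaled by each coordinate's own excursion
  wobble <- NULL
  if (config$shape_variability > 0) {
    wobble <- lapply(AXES, function(ax) list(
      f = stats::runif(3, 0.3, 1.5),
      phi = stats::runif(3, 0, 2 * pi),
      c = stats::rnorm(3) / sqrt(3)))
    names(wobble) <- AXES
  }

  markers <- list()
  for (m in MARKERS) {
    base <- config$marker_amplitude_scale[[m]] * config$base_amplitude_m * p_scale
    coords <- matrix(0, nrow = 0, ncol = 3)
    cols <- lapply(AXES, function(ax) {
      amp <- base * AXIS_WEIGHTS[[ax]]
      n_sub <- 0
      jitter_sd <- 0
      for (e in effects) {
        if (e$marker == m && e$axis == ax) {
          if (e$effect_kind == "amplitude_scale") amp <- amp * e$magnitude
          if (e$effect_kind == "submovement_count") n_sub <- n_sub + round(e$magnitude)
          if (e$effect_kind == "jerk_noise_sd") jitter_sd <- jitter_sd + e$magnitude
        }
      }
      up <- minimal_jerk_profile(0, amp, half, rate)
      down <- minimal_jerk_profile(amp, 0, half, rate)
      move <- c(up, down[-1])
      if (n_sub > 0) {
        # corrective submovements: short minimal-jerk there-and-back pulses
        # superimposed on the main movement at evenly spaced onsets
        pulse_amp <- 0.15 * amp
        half_n <- max(3L, as.integer(round(0.1 * length(move))))
        pulse <- c(minimal_jerk_profile(0, pulse_amp, 1, half_n - 1),
                   minimal_jerk_profile(pulse_amp, 0, 1, half_n - 1)[-1])
        onsets <- round(seq(0.2, 0.8, length.out = n_sub) * (length(move) - length(pulse)))
        for (o in onsets) {
          idx <- (o + 1):(o + length(pulse))
          move[idx] <- move[idx] + pulse
        }
      }
      if (!is.null(wobble)) {
        # motor variability windowed by a sin^2 envelope so the rest padding
        # stays still and the movement endpoints are preserved
        w <- wobble[[ax]]
        tm <- (seq_along(move) - 1) / rate
        env <- sin(pi * (seq_along(move) - 1) / (length(move) - 1))^2
        dev <- numeric(length(move))
        for (k in 1:3) {
          dev <- dev + w$c[k] * sin(2 * pi * w$f[k] * tm + w$phi[k])
        }
        move <- move + config$shape_variability * amp * env * dev
      }
      series <- c(rep(0, n_pad), move, rep(0, n_pad))
      if (jitter_sd > 0) {
        # tremor: sinusoid in the 8-12 Hz physiological band, positional
        # sd = jitter_sd (amplitude sqrt(2) * sd)
        f_tremor <- stats::runif(1, 8, 12)
        phi <- stats::runif(1, 0, 2 * pi)
        tt <- (seq_along(series) - 1) / rate
        series <- series + sqrt(2) * jitter_sd * sin(2 * pi * f_tremor * tt + phi)
      }
      series
    })
    markers[[m]] <- do.call(cbind, stats::setNames(cols, AXES))
  }
  if (config$noise_sd > 0) {
    markers <- lapply(markers, function(mm) {
      mm + matrix(stats::rnorm(length(mm), 0, config$noise_sd),
                  nrow = nrow(mm))
    })
  }
  .Random.seed_restore(old)
  limb_recording(markers, sampling_rate_hz = rate,
                 recording_id = recording_id,
                 participant_id = as.character(participant_id),
                 class_label = class_label, side = side,
                 activity = config$activity)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full cohort of recordings
#'
#' Post-stroke participants contribute `recordings_per_limb` recordings of
#' the non-affected limb (class G0) and the same number of the affected limb
#' (class G1); control participants contribute `recordings_per_limb` per limb
#' with both limbs labelled G2. The default cohort (35 post-stroke, 19
#' control, 3 recordings per limb) therefore yields 105 G0, 105 G1 and 114 G2
#' recordings. Affected sides and control-limb sides alternate across
#' participants. Per-recording noise seeds are derived from the master seed
#' by a stable hash of the recording id.
#'
#' @param config a [simulation_config()].
#' @return list with elements `recordings` (list of [limb_recording()]) and
#'   `manifest` (data.frame: recording_id, class_label, participant_id,
#'   side, activity).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  rows <- list()
  add <- function(pid, side, class_label) {
    for (r in seq_len(config$recordings_per_limb)) {
      rid <- sprintf("%s_%s_%s_r%d", pid, side, class_label, r)
      rows[[length(rows) + 1L]] <<- data.frame(
        recording_id = rid, class_label = class_label,
        participant_id = pid, side = side, activity = config$activity,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_stroke)) {
    pid <- sprintf("S%02d", i)
    affected <- if (i %% 2L == 1L) "right" else "left"
    nonaffected <- setdiff(SIDES, affected)
    add(pid, nonaffected, "G0")
    add(pid, affected, "G1")
  }
  for (i in seq_len(config$n_control)) {
    pid <- sprintf("C%02d", i)
    add(pid, "left", "G2")
    add(pid, "right", "G2")
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recording_id = character(), class_label = character(),
               participant_id = character(), side = character(),
               activity = character(), stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    seed <- (stable_hash(row$recording_id) + config$seed) %% 2147483647L
    simulate_recording(config, row$class_label, row$participant_id,
                       side = row$side, seed = seed,
                       recording_id = row$recording_id)
  })
  names(recordings) <- manifest$recording_id
  list(recordings = recordings, manifest = manifest)
}
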