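# Shared fixtures: tiny deterministic recordings and small cohorts built in
# code so no binary data ships with the package.

make_recording <- function(n = 120, rate = 100, side = "left",
                           class_label = "G0", amp = c(FN = 0.5, LEP = 0.35,
                                                       MPH = 0.2, ACR = 0.07)) {
  tau <- seq(0, 1, length.out = n)
  bump <- sin(pi * tau)^2
  markers <- lapply(amp, function(a) {
    cbind(x = 0.05 * a * bump, y = 0.3 * a * bump, z = a * bump)
  })
  limb_recording(markers, sampling_rate_hz = rate, side = side,
                 class_label = class_label)
}

temp_path <- function(ext) tempfile(fileext = ext)

quiet_cfg <- function(...) {
  simulation_config(n_stroke = 2, n_control = 1, recordings_per_limb = 1,
                    noise_sd = 0, participant_sd = 0, shape_variability = 0,
                    rest_padding_s = 0.3,
                    movement_duration_s = 1.5, seed = 5, ...)
}
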