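# Shared fixtures: everything is generated in code, no stored data.

AX <- make_axis(400, 1800, 2)
LIB <- template_library()

# deterministic worlds
noise_zero <- function() noise_model(additive_sd = 0,
                                     baseline_coeffs = c(0, 0, 0),
                                     intensity_cv = 0)
noise_quiet <- function(cv = 0) noise_model(additive_sd = 1,
                                            baseline_coeffs = c(3, 2, 2),
                                            intensity_cv = cv)

render_at_snr <- function(template, snr, seed = NULL, noise = noise_model(),
                          integration_s = 1, axis = AX) {
  render_spectrum(template, axis, noise,
                  amplitude_for_snr(template, axis, noise, snr),
                  seed = seed, integration_s = integration_s)
}

detect_band_on <- function(spectrum, window, k_sigma = 3)
  detect_band(spectrum, window, estimate_noise_sd(spectrum), k_sigma)

hiapp_truth_map <- c(predominant = "predominant_helix_coil",
                     typeI = "typeI_turn",
                     typeII = "typeII_beta",
                     fibril = "fibril_like",
                     none = "unclassified")
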