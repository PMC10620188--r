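#' Noise model for synthetic spectra
#'
#' Additive white Gaussian noise plus a slowly varying quadratic baseline and
#' a shot-to-shot multiplicative intensity jitter. `additive_sd` is the noise
#' standard deviation at 1 s integration; realized noise scales as
#' `additive_sd / sqrt(integration_s)`. The baseline is evaluated on the
#' normalized coordinate `x = (nu - mid) / halfspan` of the axis, so the
#' coefficients are in units of `additive_sd` regardless of the span.
#'
#' @param additive_sd Additive noise sd (arb) at 1 s integration, >= 0.
#' @param baseline_coeffs Quadratic coefficients `c(b0, b1, b2)` of the
#'   baseline `b0 + b1*x + b2*x^2`.
#' @param intensity_cv Fractional shot-to-shot scale variation, >= 0.
#' @export
noise_model <- function(additive_sd = 1, baseline_coeffs = c(3, 2, 2),
                        intensity_cv = 0.1) {
  if (additive_sd < 0) stop("additive_sd must be >= 0")
  if (intensity_cv < 0) stop("intensity_cv must be >= 0")
  stopifnot(length(baseline_coeffs) == 3)
  structure(list(additive_sd = additive_sd,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 intensity_cv = intensity_cv), class = "noise_model")
}

baseline_values <- function(noise, axis) {
  v <- axis$values
  x <- (v - mean(range(v))) / (diff(range(v)) / 2)
  b <- noise$baseline_coeffs
  b[1] + b[2] * x + b[3] * x^2
}

#' Stochastic event occupancy process
#'
#' Each spectrum independently contains analyte signal with probability
#' `p_event`; an event is a dual-analyte co-occupancy with probability
#' `dual_rule`, otherwise a single draw from `mix`.
#'
#' @param p_event Per-spectrum event probability (default 0.05, the rare-event
#'   regime of a dilute bi-analyte campaign).
#' @param mix Named categorical weights over templates, summing to 1.
#' @param dual_rule Probability that an event is a dual co-occupancy.
#' @export
event_process <- function(p_event = 0.05, mix = c(MB = 0.5, NBA = 0.5),
                          dual_rule = 0.1) {
  if (p_event < 0 || p_event > 1 || dual_rule < 0 || dual_rule > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.null(names(mix)) || any(mix < 0))
    stop("mix must be a named non-negative weight vector")
  if (abs(sum(mix) - 1) > 1e-8)
    stop("mix weights must sum to 1 (got ", sum(mix), ")")
  structure(list(p_event = p_event, mix = mix, dual_rule = dual_rule),
            class = "event_process")
}

#' Amplitude scale realizing a target signal-to-noise ratio
#'
#' Returns the multiplier that brings the template's noise-free peak height
#' to `snr` times the noise model's nominal (1 s) additive sd.
#'
#' @inheritParams template_profile
#' @param noise A [noise_model()].
#' @param snr Target peak-height to noise-sd ratio.
#' @export
amplitude_for_snr <- function(template, axis, noise, snr) {
  h <- template_height(template, axis)
  if (h <= 0) stop("template has zero height; cannot set an SNR")
  # noise-free rendering: keep the peak height at `snr` in nominal sd units
  sd_ref <- if (noise$additive_sd > 0) noise$additive_sd else 1
  snr * sd_ref / h
}

render_one <- function(template, axis, noise, amplitude_scale, integration_s,
                       trap_state, session_id, time_s, label) {
  signal <- if (is.null(template)) numeric(length(axis$values))
            else template_profile(template, axis)
  jitter <- if (noise$intensity_cv > 0)
    max(1 + noise$intensity_cv * stats::rnorm(1), 0.01) else 1
  sd_eff <- noise$additive_sd / sqrt(integration_s)
  y <- signal * amplitude_scale * jitter + baseline_values(noise, axis)
  if (sd_eff > 0) y <- y + stats::rnorm(length(y), sd = sd_eff)
  new_spectrum(axis, y, trap_state = trap_state, session_id = session_id,
               time_s = time_s, integration_s = integration_s,
               label_truth = label)
}

#' Render one synthetic spectrum from a species template
#'
#' Intensity is the sum of the template's analytic band profiles times
#' `amplitude_scale` and a multiplicative shot-to-shot jitter, plus the
#' baseline and additive Gaussian noise of the noise model. The ground-truth
#' template name is stored in the spectrum metadata.
#'
#' @inheritParams amplitude_for_snr
#' @param amplitude_scale Multiplier applied to the template profile.
#' @param seed Integer seed (the RNG state is restored afterwards); `NULL`
#'   draws from the current stream.
#' @param integration_s Integration time (s); additive noise scales as
#'   `1/sqrt(integration_s)`.
#' @param trap_state,session_id,time_s Acquisition metadata.
#' @export
render_spectrum <- function(template, axis, noise = noise_model(),
                            amplitude_scale = 1, seed = NULL,
                            integration_s = 1, trap_state = NA_character_,
                            session_id = "S1", time_s = NA_real_) {
  run <- function() render_one(template, axis, noise, amplitude_scale,
                               integration_s, trap_state, session_id, time_s,
                               if (is.null(template)) "none" else template$name)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a bi-analyte (BiASERS) spectrum set
#'
#' Emulates a dilute two-dye campaign: most spectra are noise plus baseline;
#' a fraction `p_event` carry the MB and/or NBA template, scaled to the
#' requested SNR. Ground-truth labels (`none`, `single_MB`, `single_NBA`,
#' `dual_MB_NBA`) are stored in the metadata, and spectra are spread over
#' `n_sessions` parallel sessions.
#'
#' @param n Number of spectra (>= 1).
#' @param process An [event_process()].
#' @param noise A [noise_model()].
#' @param axis A [make_axis()] grid.
#' @param seed Integer seed (required for reproducibility).
#' @param snr Peak-height SNR of an event's template (default 8).
#' @param library Template library supplying `MB` and `NBA`.
#' @param n_sessions Number of parallel sessions for the session metadata.
#' @param integration_s Integration time per spectrum (s).
#' @return A `sers_set`.
#' @export
simulate_biasers_set <- function(n, process = event_process(),
                                 noise = noise_model(), axis = make_axis(),
                                 seed = 1, snr = 8,
                                 library = template_library(),
                                 n_sessions = 20, integration_s = 1) {
  stopifnot(n >= 1)
  tnames <- names(process$mix)
  if (!all(tnames %in% names(library)))
    stop("mix names must match template library entries")
  scales <- vapply(tnames, function(nm)
    amplitude_for_snr(library[[nm]], axis, noise, snr), numeric(1))
  withr::with_seed(seed, {
    draw_event <- stats::runif(n) < process$p_event
    draw_dual <- stats::runif(n) < process$dual_rule
    draw_mix <- sample(tnames, n, replace = TRUE, prob = process$mix)
    cols <- matrix(0, length(axis$values), n)
    labels <- character(n)
    sess <- sprintf("S%02d", 1 + (seq_len(n) - 1) %% n_sessions)
    for (i in seq_len(n)) {
      if (!draw_event[i]) {
        tpl <- NULL; sc <- 1; labels[i] <- "none"
      } else if (draw_dual[i]) {
        # superpose the fully scaled species templates (no cross terms)
        bands <- unlist(lapply(tnames, function(nm) {
          lapply(library[[nm]]$bands, function(b) {
            b$area <- b$area * scales[[nm]]; b
          })
        }), recursive = FALSE)
        labels[i] <- paste0("dual_", paste(tnames, collapse = "_"))
        tpl <- species_template(labels[i], bands)
        sc <- 1
      } else {
        tpl <- library[[draw_mix[i]]]
        sc <- scales[[draw_mix[i]]]
        labels[i] <- paste0("single_", draw_mix[i])
      }
      s <- render_one(tpl, axis, noise, sc, integration_s, NA_character_,
                      sess[i], i - 1, labels[i])
      cols[, i] <- s$intensity
    }
    meta <- data.frame(trap_state = NA_character_, session_id = sess,
                       time_s = as.numeric(seq_len(n) - 1),
                       integration_s = integration_s, label_truth = labels,
                       stringsAsFactors = FALSE)
    new_spectrum_set(axis, cols, meta)
  })
}

#' Simulate a trap on/off switching series
#'
#' Alternating on/off spectra (on first), `2 * n_cycles` in total. On-state
#' spectra carry the analyte template with shot-to-shot scale variation
#' `noise$intensity_cv`; off-state spectra are baseline plus noise only.
#'
#' @param n_cycles Number of on/off cycles (default 12).
#' @param on_template Template present in the on state (default the
#'   junction-geometry NBA template with its 1645 cm^-1 ring stretch).
#' @param integration_s Per-state integration time (s); the default 5 s
#'   mirrors time-averaged switching acquisition.
#' @inheritParams simulate_biasers_set
#' @export
simulate_switching_series <- function(n_cycles = 12,
                                      on_template = template_library()$NBA_junction,
                                      noise = noise_model(intensity_cv = 0.15),
                                      axis = make_axis(), seed = 1, snr = 20,
                                      integration_s = 5) {
  stopifnot(n_cycles >= 1)
  sc <- amplitude_for_snr(on_template, axis, noise, snr)
  withr::with_seed(seed, {
    n <- 2L * n_cycles
    cols <- matrix(0, length(axis$values), n)
    states <- rep(c("on", "off"), n_cycles)
    for (i in seq_len(n)) {
      on <- states[i] == "on"
      s <- render_one(if (on) on_template else NULL, axis, noise, sc,
                      integration_s, states[i], "S01",
                      (i - 1) * integration_s,
                      if (on) on_template$name else "none")
      cols[, i] <- s$intensity
    }
    meta <- data.frame(trap_state = states, session_id = "S01",
                       time_s = (seq_len(n) - 1) * integration_s,
                       integration_s = integration_s,
                       label_truth = ifelse(states == "on", on_template$name,
                                            "none"),
                       stringsAsFactors = FALSE)
    new_spectrum_set(axis, cols, meta)
  })
}

#' Simulate an amylin (hIAPP) spectrum set
#'
#' Each spectrum independently carries one hIAPP species template drawn from
#' `species_probs` (names `predominant`, `typeI`, `typeII`, optionally
#' `fibril`); the probability remainder yields below-threshold (noise-only)
#' spectra. Truth labels store the species name.
#'
#' @param species_probs Named probabilities summing to at most 1.
#' @inheritParams simulate_biasers_set
#' @export
simulate_hiapp_set <- function(n,
                               species_probs = c(predominant = 0.96,
                                                 typeI = 0.02, typeII = 0.02),
                               noise = noise_model(), axis = make_axis(),
                               seed = 1, snr = 8,
                               library = template_library(),
                               n_sessions = 20, integration_s = 1) {
  stopifnot(n >= 1)
  if (any(species_probs < 0) || sum(species_probs) > 1 + 1e-9)
    stop("species_probs must be non-negative and sum to at most 1")
  map <- c(predominant = "HIAPP_helix_coil", typeI = "HIAPP_typeI",
           typeII = "HIAPP_typeII", fibril = "HIAPP_fibril")
  if (!all(names(species_probs) %in% names(map)))
    stop("species_probs names must be among ", paste(names(map), collapse = ", "))
  tnames <- map[names(species_probs)]
  scales <- stats::setNames(vapply(tnames, function(nm)
    amplitude_for_snr(library[[nm]], axis, noise, snr), numeric(1)),
    unname(tnames))
  withr::with_seed(seed, {
    draw <- sample(c(names(species_probs), "none"), n, replace = TRUE,
                   prob = c(species_probs, 1 - sum(species_probs)))
    cols <- matrix(0, length(axis$values), n)
    sess <- sprintf("S%02d", 1 + (seq_len(n) - 1) %% n_sessions)
    for (i in seq_len(n)) {
      if (draw[i] == "none") {
        s <- render_one(NULL, axis, noise, 1, integration_s, NA_character_,
                        sess[i], i - 1, "none")
      } else {
        nm <- map[[draw[i]]]
        s <- render_one(library[[nm]], axis, noise, scales[[nm]],
                        integration_s, NA_character_, sess[i], i - 1, draw[i])
      }
      cols[, i] <- s$intensity
    }
    meta <- data.frame(trap_state = NA_character_, session_id = sess,
                       time_s = as.numeric(seq_len(n) - 1),
                       integration_s = integration_s, label_truth = draw,
                       stringsAsFactors = FALSE)
    new_spectrum_set(axis, cols, meta)
  })
}
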