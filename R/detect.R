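#' Detection window
#'
#' A named wavenumber interval searched for a band, optionally carrying the
#' support of its local linear baseline. Without a baseline region the
#' baseline is the chord through the window edges; with one, a line is
#' fitted over the points of `baseline_region` outside `baseline_exclude`
#' (flanks clear of any declared band), which avoids swallowing the tails
#' of a band that fills most of the window.
#'
#' @param name Window label.
#' @param lo,hi Bounds in cm^-1, `lo < hi`.
#' @param baseline_region Optional interval over which the baseline line is
#'   fitted.
#' @param baseline_exclude Optional interval (the band complex) removed from
#'   the baseline fit.
#' @export
detection_window <- function(name, lo, hi, baseline_region = NULL,
                             baseline_exclude = NULL) {
  if (!(lo < hi)) stop("detection window requires lo < hi")
  structure(list(name = name, lo = lo, hi = hi,
                 baseline_region = baseline_region,
                 baseline_exclude = baseline_exclude),
            class = "detection_window")
}

#' Default bi-analyte detection windows
#'
#' The two informative spectral regions of the MB/NBA experiment split at
#' the midpoint between the 1630 and 1650 cm^-1 assignments:
#' `marker600` = 590--610, `mb1630` = 1620--1640, `nba1650` = 1642--1662.
#' The two high-wavenumber windows share one baseline support flanking the
#' full 1620--1662 band complex, so a band in either window does not bias
#' the other's baseline.
#' @export
biasers_windows <- function() {
  list(marker600 = detection_window("marker600", 590, 610,
                                    baseline_region = c(578, 622),
                                    baseline_exclude = c(588, 612)),
       mb1630 = detection_window("mb1630", 1620, 1640,
                                 baseline_region = c(1604, 1678),
                                 baseline_exclude = c(1618, 1664)),
       nba1650 = detection_window("nba1650", 1642, 1662,
                                  baseline_region = c(1604, 1678),
                                  baseline_exclude = c(1618, 1664)))
}

#' Three-sigma band detection in a window
#'
#' The candidate is the maximum of the SG-smoothed intensity above a local
#' linear (chord) baseline through the window edges. The band is `present`
#' when the candidate height reaches `k_sigma` times the noise sd *and* at
#' least 3 consecutive points exceed `k_sigma/2` times the noise sd (a
#' multiplicity control against single-pixel noise). The center is refined
#' by parabolic interpolation through the three points around the maximum
#' and clipped into the window (with a warning) if the refinement escapes it.
#'
#' @param spectrum A (background-subtracted) `sers_spectrum`.
#' @param window A [detection_window()].
#' @param noise A [estimate_noise_sd()] result (or any list with an `sd`
#'   field). A zero sd with non-zero signal yields `snr = Inf` and a
#'   `sigma_zero` flag.
#' @param k_sigma Detection threshold in noise-sd units (default 3).
#' @param smooth [sg_params()] for the smoothing pass, or `NULL` for none.
#' @return An object of class `band_hit`: fields `window`, `present`,
#'   `center`, `height`, `snr`, `flags`.
#' @export
detect_band <- function(spectrum, window, noise, k_sigma = 3,
                        smooth = sg_params(11, 3, 0)) {
  stopifnot(inherits(spectrum, "sers_spectrum"),
            inherits(window, "detection_window"))
  idx <- axis_which(spectrum$axis, window$lo, window$hi)
  if (length(idx) < 5)
    stop("window ", window$name, " covers fewer than 5 grid points")
  y <- spectrum$intensity
  if (!is.null(smooth)) y <- drop(sg_apply_matrix(y, smooth,
                                                  spectrum$axis$step))
  nu <- spectrum$axis$values[idx]
  yy <- y[idx]
  if (!is.null(window$baseline_region)) {
    bidx <- axis_which(spectrum$axis, window$baseline_region[1],
                       window$baseline_region[2])
    if (!is.null(window$baseline_exclude)) {
      bnu <- spectrum$axis$values[bidx]
      bidx <- bidx[bnu < window$baseline_exclude[1] |
                   bnu > window$baseline_exclude[2]]
    }
    if (length(bidx) < 4) stop("baseline support of window ", window$name,
                               " holds fewer than 4 points")
    co <- stats::lm.fit(cbind(1, spectrum$axis$values[bidx]),
                        y[bidx])$coefficients
    base <- co[1] + co[2] * nu
  } else {
    base <- seq(yy[1], yy[length(yy)], length.out = length(yy))
  }
  dev <- yy - base
  imax <- which.max(dev)
  height <- dev[imax]
  sigma <- noise$sd
  flags <- character(0)
  # a maximum at the window edge that keeps rising just outside belongs to
  # a neighboring band, not to this window
  neighbor <- FALSE
  if (imax == 1 && idx[1] > 1) {
    b0 <- if (is.null(window$baseline_region)) base[1]
          else base[1] - (base[2] - base[1])
    neighbor <- (y[idx[1] - 1] - b0) > height
  } else if (imax == length(yy) && idx[length(idx)] < length(y)) {
    nidx <- length(idx)
    b0 <- if (is.null(window$baseline_region)) base[nidx]
          else base[nidx] + (base[2] - base[1])
    neighbor <- (y[idx[nidx] + 1] - b0) > height
  }
  if (neighbor) flags <- c(flags, "neighbor_band")
  if (sigma <= 1e-3 * max(diff(range(y)), .Machine$double.xmin)) {
    # noise-free (up to detrending residuals of band tails): "signal" means
    # above the numerical noise of the whole trace
    tol0 <- 1e-3 * max(diff(range(y)), .Machine$double.eps)
    present <- height > tol0 && !neighbor
    snr <- if (height > tol0) Inf else 0
    if (present) flags <- c(flags, "sigma_zero")
  } else {
    snr <- height / sigma
    run <- rle(dev >= k_sigma * sigma / 2)
    has_run <- any(run$lengths[run$values] >= 3)
    present <- (snr >= k_sigma) && has_run && !neighbor
  }
  center <- NA_real_
  if (present) {
    if (imax == 1 || imax == length(yy)) {
      # maximum pinned at the window boundary (and not rejected as a
      # neighboring band): report the boundary position
      center <- nu[imax]
      warning("band center clipped into window ", window$name)
      flags <- c(flags, "edge_clipped")
    } else {
      # refine on the smoothed trace itself: the baseline only gates
      # presence and height, a tilted chord must not displace the apex
      a <- yy[imax - 1]; b <- yy[imax]; cc <- yy[imax + 1]
      denom <- a - 2 * b + cc
      offs <- if (denom < -1e-12) (a - cc) / (2 * denom) else 0
      center <- nu[imax] + offs * spectrum$axis$step
      if (center < window$lo || center > window$hi) {
        warning("band center clipped into window ", window$name)
        center <- min(max(center, window$lo), window$hi)
        flags <- c(flags, "edge_clipped")
      }
    }
  }
  structure(list(window = window, present = present, center = center,
                 height = height, snr = snr, flags = flags),
            class = "band_hit")
}

#' Classify one bi-analyte spectrum from its three band hits
#'
#' Decision rules of the single-molecule evidence chain: a 1650 cm^-1 hit
#' together with the 600 cm^-1 marker (and no 1630 hit) is a single-NBA
#' event; a 1630 hit without the 600 marker and without 1650 is a single-MB
#' event; simultaneous 1630 and 1650 hits are a dual event; anything else is
#' no event. Total over all hit combinations.
#'
#' @param hits Named list with `band_hit` entries `marker600`, `mb1630`,
#'   `nba1650` (or logical presence flags).
#' @return One of `"none"`, `"single_MB"`, `"single_NBA"`, `"dual_MB_NBA"`.
#' @export
classify_biasers <- function(hits) {
  p <- vapply(hits[c("marker600", "mb1630", "nba1650")], function(h)
    if (inherits(h, "band_hit")) h$present else isTRUE(h), logical(1))
  if (p[["mb1630"]] && p[["nba1650"]]) return("dual_MB_NBA")
  if (p[["nba1650"]] && p[["marker600"]]) return("single_NBA")
  if (p[["mb1630"]] && !p[["marker600"]]) return("single_MB")
  "none"
}

#' Detect and classify every spectrum of a bi-analyte set
#'
#' Per spectrum: estimate the noise sd in the quiet region, run
#' [detect_band()] in the three windows, then [classify_biasers()].
#'
#' @param set A `sers_set`.
#' @param windows Named window list as from [biasers_windows()].
#' @param k_sigma Detection threshold.
#' @param quiet_region Noise-estimation region.
#' @return A data.frame with one row per spectrum: `label`, per-window
#'   presence, centers and SNRs.
#' @export
classify_biasers_set <- function(set, windows = biasers_windows(),
                                 k_sigma = 3, quiet_region = c(1750, 1800)) {
  stopifnot(inherits(set, "sers_set"))
  n <- n_spectra(set)
  smoothed <- sg_apply_matrix(set$intensities, sg_params(11, 3, 0),
                              set$axis$step)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- get_spectrum(set, i)
    ns <- estimate_noise_sd(s, quiet_region)
    sm <- s
    sm$intensity <- smoothed[, i]
    hits <- lapply(windows, function(w)
      detect_band(sm, w, ns, k_sigma, smooth = NULL))
    rows[[i]] <- data.frame(
      label = classify_biasers(hits),
      marker600 = hits$marker600$present,
      mb1630 = hits$mb1630$present,
      nba1650 = hits$nba1650$present,
      center600 = hits$marker600$center,
      center1630 = hits$mb1630$center,
      center1650 = hits$nba1650$center,
      snr600 = hits$marker600$snr,
      snr1630 = hits$mb1630$snr,
      snr1650 = hits$nba1650$snr,
      noise_sd = ns$sd,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Event statistics of a classified spectrum set
#'
#' @param set The classified `sers_set`.
#' @param labels Character vector of per-spectrum event labels.
#' @return List with `counts` (all four labels), `detected_fraction`
#'   (share of spectra with any event) and `histogram` (event labels only).
#' @export
event_summary <- function(set, labels) {
  stopifnot(inherits(set, "sers_set"))
  if (length(labels) != n_spectra(set))
    stop("one label per spectrum required (", length(labels), " labels for ",
         n_spectra(set), " spectra)")
  lv <- c("none", "single_MB", "single_NBA", "dual_MB_NBA")
  counts <- table(factor(labels, levels = lv))
  list(counts = as.list(counts),
       detected_fraction = unname(sum(counts[-1]) / length(labels)),
       histogram = as.list(counts[-1]))
}

#' Reproducibility of a trap on/off switching series
#'
#' Measures the analyte peak height (smoothed, above the window chord
#' baseline) in every spectrum of an alternating on/off series and reports
#' the relative standard deviation of the on-state heights, the on/off
#' contrast, and whether any off-state spectrum passes the `k_sigma`
#' detection rule (a protocol violation).
#'
#' @param series A `sers_set` with `trap_state` metadata and >= 2 on states.
#' @param analyte_window [detection_window()] of the analyte band (default
#'   1635--1655 cm^-1 for the junction-geometry 1645 cm^-1 ring stretch).
#' @param k_sigma Detection threshold for the off-state check.
#' @param quiet_region Noise-estimation region.
#' @return List with `on_heights`, `off_heights`, `rsd_percent`, `contrast`,
#'   `off_state_violation`.
#' @export
switching_rsd <- function(series,
                          analyte_window = detection_window(
                            "nba1645", 1635, 1655,
                            baseline_region = c(1615, 1675),
                            baseline_exclude = c(1633, 1657)),
                          k_sigma = 3, quiet_region = c(1750, 1800)) {
  stopifnot(inherits(series, "sers_set"))
  st <- series$meta$trap_state
  if (all(is.na(st))) stop("series carries no trap_state metadata")
  on_idx <- which(st == "on")
  off_idx <- which(st == "off")
  if (length(on_idx) < 2) stop("need at least 2 on-state spectra")
  measure <- function(i) {
    s <- get_spectrum(series, i)
    ns <- estimate_noise_sd(s, quiet_region)
    detect_band(s, analyte_window, ns, k_sigma)
  }
  on_hits <- lapply(on_idx, measure)
  off_hits <- lapply(off_idx, measure)
  on_h <- vapply(on_hits, `[[`, 0, "height")
  off_h <- vapply(off_hits, `[[`, 0, "height")
  violation <- any(vapply(off_hits, `[[`, FALSE, "present"))
  if (violation)
    warning("off-state spectra pass the ", k_sigma,
            "-sigma rule: analyte present with the trap off")
  rsd <- 100 * stats::sd(on_h) / mean(on_h)
  contrast <- mean(on_h) / max(mean(off_h), .Machine$double.eps)
  list(on_heights = on_h, off_heights = off_h, rsd_percent = rsd,
       contrast = contrast, off_state_violation = violation)
}
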