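# Amide-I second-derivative band analysis, tyrosine doublet and nu8a
# markers, disulfide conformation markers, and the hIAPP species decision
# table built on them.

#' Amide-I band centers from the second-derivative trace
#'
#' Local maxima of `-d2 I / d nu^2` over the amide I region that rise above
#' 3x the second-derivative noise floor (estimated in the quiet region) and
#' above a fraction `rel_keep` of the strongest maximum (secondary-peak
#' culling against correlated-noise bumps). Centers are refined by a 7-point
#' quadratic fit; each band's width is reported both as the half-maximum
#' width of its second-derivative lobe and as the deconvolved Lorentzian
#' FWHM fitted on the raw spectrum.
#'
#' @param spectrum A `sers_spectrum` covering the region and the quiet region.
#' @param region Analysis interval, default `c(1550, 1750)`.
#' @param sg_d2,sg_smooth SG parameters of the derivative and pre-smoothing
#'   stages (see [second_derivative_region()]).
#' @param k_floor Noise-floor multiplier (default 3).
#' @param rel_keep Relative culling threshold (default 0.4).
#' @param quiet_region Band-free interval for the derivative noise floor;
#'   the default ends at 1776 cm^-1 so that it stays clear of the
#'   amplified-variance edge kernels of the two cascaded filters (12 points
#'   at a 1800 cm^-1 axis end).
#' @return Object of class `amide_bands`: `centers`, `widths` (fitted band
#'   FWHM, cm^-1), `d2_widths`, `heights` (second-derivative amplitudes),
#'   `trace` (the `-d2` spectrum), `floor`.
#' @export
amide_band_centers <- function(spectrum, region = c(1550, 1750),
                               sg_d2 = sg_params(15, 3, 2),
                               sg_smooth = sg_params(11, 3, 0),
                               k_floor = 3, rel_keep = 0.4,
                               quiet_region = c(1744, 1776)) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  # full-axis derivative so the floor and the region share one trace
  full <- second_derivative_region(spectrum,
                                   region = range(spectrum$axis$values),
                                   params = sg_d2, smooth = sg_smooth)
  floor_est <- estimate_noise_sd(full, quiet_region)
  idx <- axis_which(full$axis, region[1], region[2])
  nu <- full$axis$values[idx]
  y <- full$intensity[idx]
  step <- full$axis$step
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max)
  thr <- k_floor * floor_est$sd
  cand <- cand[y[cand] >= thr]
  if (length(cand) > 0) cand <- cand[y[cand] >= rel_keep * max(y[cand])]
  centers <- widths_d2 <- widths_fit <- heights <- numeric(0)
  for (i in cand) {
    j <- max(1, i - 3):min(n, i + 3)
    co <- stats::lm.fit(cbind(1, nu[j] - nu[i], (nu[j] - nu[i])^2),
                        y[j])$coefficients
    ctr <- if (co[3] < 0) nu[i] - co[2] / (2 * co[3]) else nu[i]
    ctr <- min(max(ctr, nu[max(1, i - 1)]), nu[min(n, i + 1)])
    hm <- y[i] / 2
    l <- i; while (l > 1 && y[l] > hm) l <- l - 1
    r <- i; while (r < n && y[r] > hm) r <- r + 1
    xl <- if (y[l] <= hm && l < i)
      nu[l] + (hm - y[l]) / (y[l + 1] - y[l]) * step else nu[l]
    xr <- if (y[r] <= hm && r > i)
      nu[r - 1] + (y[r - 1] - hm) / (y[r - 1] - y[r]) * step else nu[r]
    centers <- c(centers, ctr)
    widths_d2 <- c(widths_d2, xr - xl)
    heights <- c(heights, y[i])
    widths_fit <- c(widths_fit, fit_band_fwhm(spectrum, ctr))
  }
  o <- order(centers)
  structure(list(centers = centers[o], widths = widths_fit[o],
                 d2_widths = widths_d2[o], heights = heights[o],
                 trace = full, floor = floor_est$sd, region = region),
            class = "amide_bands")
}

# Deconvolved Lorentzian FWHM of one band on the raw spectrum: linear least
# squares of amplitude + linear baseline at each gamma of a grid, keeping
# the gamma with minimal residual sum of squares.
fit_band_fwhm <- function(spectrum, center, halfspan = 45,
                          gammas = seq(6, 44, 0.5)) {
  rng <- range(spectrum$axis$values)
  lo <- max(rng[1], center - halfspan)
  hi <- min(rng[2], center + halfspan)
  idx <- axis_which(spectrum$axis, lo, hi)
  nu <- spectrum$axis$values[idx]
  y <- spectrum$intensity[idx]
  best_g <- gammas[1]
  best_rss <- Inf
  for (g in gammas) {
    X <- cbind(1, nu - center, lorentz_unit(nu, center, g))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best_g <- g }
  }
  best_g
}

#' Tyrosine Fermi-doublet intensity ratio I830/I854
#'
#' Two estimators over the doublet region:
#' `"fit"` (default) models the region as two fixed-center Lorentzians plus
#' a linear baseline, with the shared linewidth chosen on a grid by residual
#' minimization, and reports the fitted area ratio with a delta-method
#' standard error. `"integration"` integrates each band window above its
#' chord baseline (trapezoid) after SG smoothing. Both are invariant under
#' global intensity scaling and under adding any linear baseline.
#'
#' @param spectrum A `sers_spectrum` covering the region.
#' @param method `"fit"` or `"integration"`.
#' @param centers Doublet band centers (cm^-1).
#' @param region Fit region, default `c(815, 870)`.
#' @param windows Integration windows for `"integration"`.
#' @param gammas Linewidth grid for `"fit"`.
#' @return Object of class `doublet_ratio`: `i830`, `i854`, `ratio`,
#'   `ratio_se` (fit method), `method`, `defined`.
#' @export
doublet_ratio <- function(spectrum, method = c("fit", "integration"),
                          centers = c(830, 854), region = c(815, 870),
                          windows = list(c(822, 840), c(846, 864)),
                          gammas = seq(6, 18, 1)) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  method <- match.arg(method)
  if (method == "fit") {
    idx <- axis_which(spectrum$axis, region[1], region[2])
    nu <- spectrum$axis$values[idx]
    y <- spectrum$intensity[idx]
    best <- NULL
    for (g in gammas) {
      X <- cbind(1, nu - mean(nu),
                 lorentz_unit(nu, centers[1], g),
                 lorentz_unit(nu, centers[2], g))
      f <- stats::lm.fit(X, y)
      rss <- sum(f$residuals^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, co = f$coefficients, X = X, g = g)
    }
    a830 <- best$co[3]; a854 <- best$co[4]
    dof <- length(y) - 4
    s2 <- best$rss / max(dof, 1)
    V <- s2 * solve(crossprod(best$X))
    se <- if (a854 > 0)
      abs(a830 / a854) * sqrt(V[3, 3] / a830^2 + V[4, 4] / a854^2 -
                                2 * V[3, 4] / (a830 * a854)) else NA_real_
    i830 <- a830; i854 <- a854
  } else {
    sm <- sg_filter(spectrum, sg_params(11, 3, 0))
    integ <- function(w) {
      idx <- axis_which(sm$axis, w[1], w[2])
      yy <- sm$intensity[idx]
      base <- seq(yy[1], yy[length(yy)], length.out = length(yy))
      dev <- yy - base
      sum((dev[-1] + dev[-length(dev)]) / 2) * sm$axis$step
    }
    i830 <- integ(windows[[1]])
    i854 <- integ(windows[[2]])
    se <- NA_real_
  }
  defined <- is.finite(i854) && i854 > 0
  if (!defined) warning("I854 is non-positive; doublet ratio undefined")
  structure(list(i830 = unname(i830), i854 = unname(i854),
                 ratio = if (defined) unname(i830 / i854) else NA_real_,
                 ratio_se = unname(se), method = method, defined = defined),
            class = "doublet_ratio")
}

#' Position of the tyrosine nu8a ring-stretching band
#'
#' Center of the dominant band in the 1595--1630 cm^-1 search window via the
#' three-sigma detection machinery: 1620 cm^-1 for the +1 charge state,
#' downshifted to 1602 cm^-1 for the -2 state.
#'
#' @param spectrum A `sers_spectrum`.
#' @param noise A noise estimate; computed from `quiet_region` when `NULL`.
#' @param window Search interval.
#' @param quiet_region Noise-estimation region.
#' @return Center (cm^-1), or `NA` when no band passes the 3-sigma rule.
#' @export
v8a_position <- function(spectrum, noise = NULL, window = c(1595, 1630),
                         quiet_region = c(1750, 1800)) {
  if (is.null(noise)) noise <- estimate_noise_sd(spectrum, quiet_region)
  win <- detection_window("v8a", window[1], window[2],
                          baseline_region = c(1565, 1660),
                          baseline_exclude = c(1583, 1642))
  hit <- detect_band(spectrum, win, noise)
  if (hit$present) hit$center else NA_real_
}

#' Disulfide conformation marker
#'
#' Three-sigma detection in the 515--531 cm^-1 (gauche-gauche-trans /
#' trans-gauche-gauche disulfide) and 482--498 cm^-1 (strained disulfide)
#' windows.
#'
#' @inheritParams v8a_position
#' @return List with `state` (`"ggt_tgg_523"`, `"strained_490"`, `"both"` or
#'   `"absent"`) and the two `band_hit`s with their heights.
#' @export
disulfide_marker <- function(spectrum, noise = NULL,
                             quiet_region = c(1750, 1800)) {
  if (is.null(noise)) noise <- estimate_noise_sd(spectrum, quiet_region)
  h523 <- detect_band(spectrum,
                      detection_window("ss523", 515, 531,
                                       baseline_region = c(468, 545),
                                       baseline_exclude = c(480, 533)),
                      noise)
  h490 <- detect_band(spectrum,
                      detection_window("ss490", 482, 498,
                                       baseline_region = c(468, 545),
                                       baseline_exclude = c(480, 533)),
                      noise)
  state <- if (h523$present && h490$present) "both"
           else if (h523$present) "ggt_tgg_523"
           else if (h490$present) "strained_490"
           else "absent"
  list(state = state, hit523 = h523, hit490 = h490)
}

#' Classification thresholds for hIAPP species calls
#'
#' @param tol_amide Position tolerance around the nominal amide-I centers
#'   (cm^-1).
#' @param amide_window Interval whose second-derivative centers count as
#'   amide I bands.
#' @param width_ref Reference FWHM of the predominant amide band (cm^-1).
#' @param broad_mult Broadness multiplier: type I requires a fitted width of
#'   at least `broad_mult * width_ref`.
#' @param ratio_hi Doublet-ratio threshold separating "about 1" from "> 1"
#'   (recorded as evidence).
#' @param tol_amideIII Tolerance around the 1226 cm^-1 amide III marker.
#' @export
hiapp_rules <- function(tol_amide = 4, amide_window = c(1640, 1700),
                        width_ref = 14, broad_mult = 1.5, ratio_hi = 1.2,
                        tol_amideIII = 6) {
  list(tol_amide = tol_amide, amide_window = amide_window,
       width_ref = width_ref, broad_mult = broad_mult, ratio_hi = ratio_hi,
       tol_amideIII = tol_amideIII)
}

#' Classify one hIAPP spectrum into its spectral species
#'
#' Decision table over the amide-I second-derivative centers (restricted to
#' the amide I window), the fitted band width, the amide III region and the
#' disulfide marker:
#' \itemize{
#' \item exactly one center at 1656 +/- tol, not broad: predominant
#'   helix-coil;
#' \item exactly one center at 1668 +/- tol with fitted width >=
#'   `broad_mult * width_ref`: type I (turn);
#' \item two centers matching 1655 +/- tol and 1674 +/- tol: type II
#'   (helix-coil + beta-sheet);
#' \item one center at 1674 +/- tol with an amide III band at 1226 +/- tol
#'   or a strained-disulfide 490 cm^-1 marker: fibril-like;
#' \item otherwise unclassified.
#' }
#' The tyrosine doublet ratio and the disulfide state are returned as
#' evidence; the ratio does not gate the type I/II calls because its
#' single-spectrum precision at realistic SNR is far below the separation
#' of the species (see the methods vignette).
#'
#' @param spectrum A `sers_spectrum`.
#' @param rules A [hiapp_rules()] list.
#' @param noise Optional noise estimate (computed when `NULL`).
#' @return Object of class `species_call`: `call` and an `evidence` list.
#' @export
classify_hiapp <- function(spectrum, rules = hiapp_rules(), noise = NULL) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  if (is.null(noise)) noise <- estimate_noise_sd(spectrum)
  ab <- amide_band_centers(spectrum)
  keep <- ab$centers >= rules$amide_window[1] &
          ab$centers <= rules$amide_window[2]
  ctr <- ab$centers[keep]
  wid <- ab$widths[keep]
  dr <- doublet_ratio(spectrum)
  ss <- disulfide_marker(spectrum, noise)
  a3 <- detect_band(spectrum,
                    detection_window("amideIII_1226",
                                     1226 - rules$tol_amideIII,
                                     1226 + rules$tol_amideIII), noise)
  near <- function(x, target) abs(x - target) <= rules$tol_amide
  broad <- wid >= rules$broad_mult * rules$width_ref
  call <- "unclassified"
  if (length(ctr) == 1 && near(ctr, 1656) && !broad[1]) {
    call <- "predominant_helix_coil"
  } else if (length(ctr) == 1 && near(ctr, 1668) && broad[1]) {
    call <- "typeI_turn"
  } else if (length(ctr) == 2 && near(ctr[1], 1655) && near(ctr[2], 1674)) {
    call <- "typeII_beta"
  } else if (length(ctr) == 1 && near(ctr, 1674) &&
             (a3$present || ss$state %in% c("strained_490", "both"))) {
    call <- "fibril_like"
  }
  structure(list(call = call,
                 evidence = list(amide_centers = ctr, amide_widths = wid,
                                 doublet_ratio = dr$ratio,
                                 disulfide = ss$state,
                                 amideIII_1226 = a3$present,
                                 ratio_flag = if (is.na(dr$ratio)) NA
                                   else dr$ratio > rules$ratio_hi)),
            class = "species_call")
}

#' Species census of a classified spectrum set
#'
#' Classifies every spectrum, then reports counts and fractions per species
#' and the per-spectrum min-max-normalized second-derivative map over the
#' amide I region (rows ordered by acquisition), the numeric analogue of a
#' spectral mapping figure.
#'
#' @param set A `sers_set`.
#' @param rules A [hiapp_rules()] list.
#' @param region Amide I mapping region.
#' @return List with `calls` (character vector), `counts`, `fractions` and
#'   `map` (spectra x points matrix).
#' @export
species_census <- function(set, rules = hiapp_rules(),
                           region = c(1550, 1750)) {
  stopifnot(inherits(set, "sers_set"))
  if (n_spectra(set) == 0) stop("empty spectrum set")
  calls <- vapply(seq_len(n_spectra(set)), function(i)
    classify_hiapp(get_spectrum(set, i), rules)$call, character(1))
  lv <- c("predominant_helix_coil", "typeI_turn", "typeII_beta",
          "fibril_like", "unclassified")
  counts <- table(factor(calls, levels = lv))
  d2 <- second_derivative_region(get_spectrum(set, 1), region)
  idx <- axis_which(d2$axis, region[1], region[2])
  map <- t(vapply(seq_len(n_spectra(set)), function(i) {
    tr <- second_derivative_region(get_spectrum(set, i), region)$intensity
    rng <- range(tr)
    if (diff(rng) <= 0) rep(0, length(tr))
    else (tr - rng[1]) / diff(rng)
  }, numeric(length(idx))))
  list(calls = calls, counts = as.list(counts),
       fractions = as.list(counts / length(calls)), map = map)
}
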