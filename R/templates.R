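#' Analytic peak band
#'
#' One vibrational band described by its center, full width at half maximum,
#' integrated area and lineshape. Area (not height) carries intensity-ratio
#' semantics, matching how Fermi-doublet ratios are quoted in the Raman
#' literature.
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param area Integrated band area (arb * cm^-1), >= 0.
#' @param lineshape `"lorentzian"`, `"gaussian"` or `"pseudo_voigt"`.
#' @param eta Pseudo-Voigt mixing parameter in \[0, 1\] (1 = Lorentzian).
#' @export
peak_band <- function(center, fwhm, area, lineshape = "lorentzian",
                      eta = 0.5) {
  lineshape <- match.arg(lineshape, c("lorentzian", "gaussian",
                                      "pseudo_voigt"))
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  if (!is.numeric(area) || area < 0) stop("area must be >= 0")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  structure(list(center = center, fwhm = fwhm, area = area,
                 lineshape = lineshape, eta = eta), class = "peak_band")
}

# unit-area profiles
lorentz_unit <- function(nu, center, fwhm)
  (2 / (pi * fwhm)) / (1 + ((nu - center) / (fwhm / 2))^2)
gauss_unit <- function(nu, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(nu - center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

#' Evaluate a band profile on a wavenumber grid
#' @param band A [peak_band()].
#' @param nu Numeric vector of wavenumbers (cm^-1).
#' @export
band_profile <- function(band, nu) {
  base <- switch(band$lineshape,
    lorentzian = lorentz_unit(nu, band$center, band$fwhm),
    gaussian = gauss_unit(nu, band$center, band$fwhm),
    pseudo_voigt = band$eta * lorentz_unit(nu, band$center, band$fwhm) +
      (1 - band$eta) * gauss_unit(nu, band$center, band$fwhm))
  band$area * base
}

#' Species template
#'
#' A generative description of one analyte as a list of bands.
#'
#' @param name Unique species name.
#' @param bands List of [peak_band()] objects (non-empty).
#' @param provenance Short free-text note on the band assignments.
#' @export
species_template <- function(name, bands, provenance = "") {
  if (length(bands) == 0) stop("a species template needs at least one band")
  stopifnot(all(vapply(bands, inherits, logical(1), "peak_band")))
  structure(list(name = name, bands = bands, provenance = provenance),
            class = "species_template")
}

#' @export
print.species_template <- function(x, ...) {
  cat(sprintf("<species_template> %s: %d bands at %s cm-1\n", x$name,
              length(x$bands),
              paste(vapply(x$bands, function(b) format(b$center),
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' Noise-free template profile on an axis
#'
#' @param template A [species_template()].
#' @param axis A [make_axis()] grid. Every band center must lie on-axis.
#' @export
template_profile <- function(template, axis) {
  rng <- range(axis$values)
  for (b in template$bands)
    if (b$center < rng[1] || b$center > rng[2])
      stop("band at ", b$center, " cm-1 of template \"", template$name,
           "\" lies outside the axis span")
  y <- numeric(length(axis$values))
  for (b in template$bands) y <- y + band_profile(b, axis$values)
  y
}

#' Peak height of a template's noise-free profile
#' @inheritParams template_profile
#' @export
template_height <- function(template, axis) max(template_profile(template, axis))

#' Built-in species template library
#'
#' Reads the packaged JSON template library: the two reporter dyes of the
#' bi-analyte experiment (NBA with its 600 cm^-1 marker and ring stretch at
#' 1650 cm^-1, at 1645 cm^-1 for the trap-switching junction; MB at
#' 1630 cm^-1 with no 600 cm^-1 band), tyrosine in its +1 and -2 charge
#' states (nu8a 1620 vs 1602 cm^-1; Fermi doublet 830/854 cm^-1 with area
#' ratio 1:1 vs 2:1) and the four amylin (hIAPP) spectral species
#' (helix-coil 1656, type I turn 1668 broad, type II 1655+1674, fibril 1674
#' with amide III 1226 and strained disulfide 490 cm^-1).
#'
#' @param path Optional path to an alternative JSON library.
#' @return Named list of [species_template()] objects.
#' @export
template_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates.json", package = "smSERS",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(tp) {
    bands <- lapply(tp$bands, function(b)
      peak_band(b$center, b$fwhm, b$area,
                lineshape = b$lineshape %||% "lorentzian",
                eta = b$eta %||% 0.5))
    species_template(tp$name, bands, tp$provenance %||% "")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("template names must be unique")
  out
}

#' pH-dependent tyrosine mixture template
#'
#' Convex combination of the +1 (fully protonated) and -2 (fully
#' deprotonated) tyrosine templates, weighted through the independent-site
#' Henderson-Hasselbalch microstate distribution of the three ionizable
#' groups (carboxyl, alpha-amino, phenol hydroxyl). Each microstate of net
#' charge q contributes with the interpolation coordinate t = (1 - q)/3
#' between the +1 endpoint (t = 0: nu8a at 1620 cm^-1, doublet 1:1) and the
#' -2 endpoint (t = 1: nu8a at 1602 cm^-1, doublet 2:1), so the doublet
#' ratio and the nu8a band weights track the mean protonation state.
#'
#' @param pH Solution pH in \[0, 14\].
#' @param pka Named numeric vector of site pKa values
#'   (`carboxyl`, `amino`, `phenol`).
#' @param library Template library holding `TYR_plus1` and `TYR_minus2`.
#' @return A [species_template()] named `"TYR_pH<pH>"`.
#' @export
tyr_mixture_template <- function(pH,
                                 pka = c(carboxyl = 2.2, amino = 9.2,
                                         phenol = 10.5),
                                 library = template_library()) {
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]")
  if (any(pka <= 0) || any(pka >= 14))
    stop("pKa values must lie strictly inside (0, 14)")
  groups <- list(
    ionizable_group("carboxyl", pka[["carboxyl"]], "acid"),
    ionizable_group("amino", pka[["amino"]], "base"),
    ionizable_group("phenol", pka[["phenol"]], "acid"))
  w <- microstate_weights(groups, pH)
  tbar <- sum(w$weight * (1 - w$charge) / 3)
  tbar <- min(max(tbar, 0), 1)
  tp1 <- library$TYR_plus1
  tm2 <- library$TYR_minus2
  scale_bands <- function(tp, f)
    lapply(tp$bands, function(b) { b$area <- b$area * f; b })
  bands <- c(scale_bands(tp1, 1 - tbar), scale_bands(tm2, tbar))
  bands <- Filter(function(b) b$area > 1e-12, bands)
  # merge coincident doublet bands contributed by both endpoints
  key <- vapply(bands, function(b)
    paste(b$center, b$fwhm, b$lineshape), character(1))
  merged <- lapply(unique(key), function(k) {
    grp <- bands[key == k]
    b <- grp[[1]]
    b$area <- sum(vapply(grp, `[[`, 0, "area"))
    b
  })
  species_template(sprintf("TYR_pH%g", pH), merged,
                   provenance = sprintf(
                     "HH mixture of TYR_plus1/TYR_minus2, t = %.4f", tbar))
}
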