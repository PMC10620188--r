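# Rayleigh-regime optical gradient force and trapping potential along the
# nanocavity axis, with the Boltzmann stability criterion.

K_BOLTZMANN <- 1.380649e-23   # J/K (exact, SI)
EPS0 <- 8.8541878128e-12      # F/m

#' Thermal energy k_B * T
#'
#' @param T Absolute temperature (K), > 0. Default 293 K (room temperature),
#'   giving 4.0e-21 J — the Brownian-motion scale a stable trap must beat.
#' @return Energy in joules.
#' @export
thermal_energy <- function(T = 293) {
  if (!is.numeric(T) || T <= 0) stop("temperature must be > 0 K")
  K_BOLTZMANN * T
}

#' Relative permittivity of silver (approximate)
#'
#' Linear interpolation of a few anchor values of the Johnson & Christy
#' optical constants for silver. Adequate for sign and order-of-magnitude
#' polarizability work, not for quantitative electromagnetics.
#'
#' @param wavelength_nm Vacuum wavelength (nm), within 400--1300.
#' @return Complex relative permittivity.
#' @export
silver_permittivity <- function(wavelength_nm) {
  wl <- c(400, 500, 532, 600, 700, 800, 900, 1000, 1064, 1200, 1300)
  re <- c(-4.0, -8.5, -11.75, -16.0, -23.4, -31.7, -41.0, -51.0, -59.4,
          -72.0, -84.0)
  im <- c(0.21, 0.30, 0.37, 0.44, 0.50, 0.45, 0.55, 0.57, 0.60, 0.65, 0.72)
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop("wavelength outside the tabulated 400-1300 nm range")
  complex(real = stats::approx(wl, re, wavelength_nm)$y,
          imaginary = stats::approx(wl, im, wavelength_nm)$y)
}

#' Clausius-Mossotti polarizability of a small sphere
#'
#' `alpha = 4 pi eps0 eps_m r^3 (eps_p - eps_m) / (eps_p + 2 eps_m)` — the
#' Rayleigh-regime dipole polarizability behind the gradient-force
#' proportionality to the field intensity.
#'
#' @param radius_nm Sphere radius (nm), > 0.
#' @param eps_particle Complex relative permittivity of the particle.
#' @param eps_medium Real relative permittivity of the medium (> 0); water
#'   at 1064 nm is about 1.77.
#' @return Complex polarizability (C m^2 / V).
#' @export
polarizability_cm <- function(radius_nm, eps_particle, eps_medium = 1.77) {
  if (radius_nm <= 0) stop("radius must be > 0")
  if (!is.numeric(eps_medium) || eps_medium <= 0)
    stop("eps_medium must be a positive real number")
  denom <- eps_particle + 2 * eps_medium
  if (abs(denom) < 1e-12)
    stop("eps_particle + 2*eps_medium is singular (Froehlich resonance)")
  r <- radius_nm * 1e-9
  4 * pi * EPS0 * eps_medium * r^3 * (eps_particle - eps_medium) / denom
}

#' Axial field-intensity profile of a trap
#'
#' @param z_nm Strictly increasing axial positions (nm); the far field is
#'   the last grid point.
#' @param e2 Relative field intensity `|E/E0|^2` at each position, >= 0.
#' @param e0_sq Reference field intensity `E0^2` (V^2/m^2).
#' @param alpha_re Real part of the particle polarizability (C m^2/V).
#' @export
trap_profile <- function(z_nm, e2, e0_sq = 1, alpha_re = NULL) {
  if (any(diff(z_nm) <= 0)) stop("z grid must be strictly increasing")
  if (length(e2) != length(z_nm)) stop("e2 must match the z grid")
  if (any(e2 < 0)) stop("relative intensity e2 must be >= 0")
  if (is.null(alpha_re))
    alpha_re <- Re(polarizability_cm(35, silver_permittivity(1064), 1.77))
  structure(list(z_nm = z_nm, e2 = e2, e0_sq = e0_sq, alpha_re = alpha_re),
            class = "trap_profile")
}

#' Gaussian hotspot profile (synthetic stand-in for a simulated field)
#'
#' @param z_range Axial range (nm).
#' @param n Number of grid points.
#' @param width_nm Gaussian 1/e^2-like width parameter (nm).
#' @param center_nm Hotspot position (nm).
#' @param peak_e2 Peak relative intensity.
#' @inheritParams trap_profile
#' @export
gaussian_hotspot_profile <- function(z_range = c(-300, 300), n = 4001,
                                     width_nm = 50, center_nm = 0,
                                     peak_e2 = 100, e0_sq = 1,
                                     alpha_re = NULL) {
  z <- seq(z_range[1], z_range[2], length.out = n)
  e2 <- peak_e2 * exp(-(z - center_nm)^2 / (2 * width_nm^2))
  trap_profile(z, e2, e0_sq, alpha_re)
}

#' Time-averaged gradient force and trapping potential
#'
#' In the Rayleigh regime the time-averaged gradient force is
#' `F(z) = 1/4 Re(alpha) E0^2 d|E/E0|^2/dz`, so the potential is
#' `U(z) = -1/4 Re(alpha) E0^2 |E/E0|^2` up to the far-field constant
#' (an exact linear-theory identity: `U = -int F dz`, `U(far) = 0`). The
#' derivative is evaluated from a cubic-spline representation of the
#' intensity profile. The trap is reported stable when the well depth
#' exceeds `stable_threshold` times the thermal energy.
#'
#' @param profile A [trap_profile()].
#' @param T Temperature (K).
#' @param stable_threshold Stability criterion in k_B T units (default 10).
#' @return Object of class `trap_result`: `z_nm`, `force_pN`, `potential_J`,
#'   `well_depth_J`, `stability_ratio`, `stable`.
#' @export
trap_force_potential <- function(profile, T = 293, stable_threshold = 10) {
  stopifnot(inherits(profile, "trap_profile"))
  z_m <- profile$z_nm * 1e-9
  pref <- 0.25 * profile$alpha_re * profile$e0_sq
  u <- -pref * (profile$e2 - profile$e2[length(profile$e2)])
  sp <- stats::splinefun(z_m, profile$e2, method = "natural")
  force <- pref * sp(z_m, deriv = 1)          # N
  depth <- max(0, -min(u))
  ratio <- depth / thermal_energy(T)
  structure(list(z_nm = profile$z_nm, force_pN = force * 1e12,
                 potential_J = u, well_depth_J = depth,
                 stability_ratio = ratio,
                 stable = ratio >= stable_threshold), class = "trap_result")
}

#' Rescale a profile's reference intensity to a target well depth
#'
#' Useful to anchor a synthetic profile to an externally known well depth
#' and then read off the stability ratio.
#'
#' @param profile A [trap_profile()].
#' @param well_depth_J Target well depth (J), > 0.
#' @export
calibrate_trap_profile <- function(profile, well_depth_J) {
  stopifnot(inherits(profile, "trap_profile"), well_depth_J > 0)
  cur <- trap_force_potential(profile)$well_depth_J
  if (cur <= 0) stop("profile has no potential well to calibrate")
  profile$e0_sq <- profile$e0_sq * well_depth_J / cur
  profile
}
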