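#' Savitzky-Golay filter parameters
#'
#' Defaults: smoothing with an 11-point (20 cm^-1 at 2 cm^-1 spacing) cubic
#' window; for second derivatives use `sg_params(15, 3, 2)`, which resolves
#' the 19 cm^-1 amide-I splitting while suppressing single-pixel noise.
#'
#' @param window_pts Odd window length in points, > `polyorder`.
#' @param polyorder Polynomial order of the local fit.
#' @param deriv_order Derivative order (0, 1 or 2), <= `polyorder`.
#' @export
sg_params <- function(window_pts = 11L, polyorder = 3L, deriv_order = 0L) {
  window_pts <- as.integer(window_pts)
  if (window_pts %% 2 == 0) stop("window_pts must be odd")
  if (window_pts <= polyorder) stop("window_pts must exceed polyorder")
  if (deriv_order > polyorder) stop("deriv_order must not exceed polyorder")
  if (!deriv_order %in% 0:2) stop("deriv_order must be 0, 1 or 2")
  structure(list(window_pts = window_pts, polyorder = as.integer(polyorder),
                 deriv_order = as.integer(deriv_order)), class = "sg_params")
}

# least-squares polynomial kernel evaluated at offset x0 (in points) from
# the window center; step converts to derivative per cm^-1
sg_kernel <- function(params, step = 1, x0 = 0) {
  m <- (params$window_pts - 1) / 2
  p <- params$polyorder
  d <- params$deriv_order
  A <- outer(seq(-m, m), 0:p, "^")
  C <- solve(crossprod(A), t(A))
  r <- numeric(p + 1)
  if (d <= p)
    for (k in d:p) r[k + 1] <- factorial(k) / factorial(k - d) * x0^(k - d)
  drop(r %*% C) / step^d
}

# filter a vector (or the columns of a matrix) with full-window edge
# handling: the first/last half-windows are evaluated from the polynomial
# fitted on the first/last full window
sg_apply_matrix <- function(y, params, step) {
  y <- as.matrix(y)
  n <- nrow(y)
  w <- params$window_pts
  m <- (w - 1) / 2
  if (n < w) stop("spectrum length (", n, ") is below window_pts (", w, ")")
  ker <- sg_kernel(params, step)
  out <- matrix(0, n, ncol(y))
  # interior via convolution
  for (j in seq_len(ncol(y))) {
    f <- stats::filter(y[, j], rev(ker), sides = 2)
    out[, j] <- as.numeric(f)
  }
  for (i in seq_len(m)) {
    k_lo <- sg_kernel(params, step, x0 = i - m - 1)
    k_hi <- sg_kernel(params, step, x0 = m + 1 - i)
    out[i, ] <- drop(k_lo %*% y[1:w, , drop = FALSE])
    out[n - i + 1, ] <- drop(k_hi %*% y[(n - w + 1):n, , drop = FALSE])
  }
  out
}

#' Savitzky-Golay smoothing / differentiation of a spectrum
#'
#' Convolution with the least-squares polynomial kernel; with
#' `deriv_order = 2` the result is the second derivative with respect to the
#' wavenumber (the grid step is accounted for). Edges are evaluated from the
#' polynomial fitted on the first/last full window. The filter is linear.
#'
#' @param spectrum A `sers_spectrum`.
#' @param params An [sg_params()] object.
#' @return A `sers_spectrum` with filtered intensities (metadata preserved).
#' @export
sg_filter <- function(spectrum, params = sg_params()) {
  stopifnot(inherits(spectrum, "sers_spectrum"), inherits(params, "sg_params"))
  out <- spectrum
  out$intensity <- drop(sg_apply_matrix(spectrum$intensity, params,
                                        spectrum$axis$step))
  out
}

#' Pointwise background subtraction
#'
#' @param spectrum,background `sers_spectrum` objects on the same axis.
#' @return `spectrum - background` with the spectrum's metadata preserved.
#' @export
subtract_background <- function(spectrum, background) {
  stopifnot(inherits(spectrum, "sers_spectrum"),
            inherits(background, "sers_spectrum"))
  if (!axis_equal(spectrum$axis, background$axis))
    stop("spectrum and background have different wavenumber axes")
  out <- spectrum
  out$intensity <- spectrum$intensity - background$intensity
  out
}

#' Negative second derivative over a spectral region
#'
#' Returns `-d2 I / d nu^2` restricted to `region` (sign flipped so band
#' centers appear as maxima, the standard second-derivative spectroscopy
#' convention). The spectrum is optionally SG-smoothed before
#' differentiation; both stages are linear, so the result of a band sum is
#' the sum of the bands' second derivatives.
#'
#' @param spectrum A `sers_spectrum`.
#' @param region Wavenumber interval, default the amide I region
#'   `c(1550, 1750)`.
#' @param params SG parameters for the derivative stage (must have
#'   `deriv_order = 2`).
#' @param smooth Optional [sg_params()] for a pre-smoothing pass, or `NULL`
#'   to differentiate the raw trace.
#' @return A `sers_spectrum` on the restricted axis holding the negative
#'   second derivative.
#' @export
second_derivative_region <- function(spectrum, region = c(1550, 1750),
                                     params = sg_params(15, 3, 2),
                                     smooth = sg_params(11, 3, 0)) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  if (params$deriv_order != 2)
    stop("params must request the second derivative")
  idx <- axis_which(spectrum$axis, region[1], region[2])
  y <- spectrum$intensity
  if (!is.null(smooth)) y <- drop(sg_apply_matrix(y, smooth,
                                                  spectrum$axis$step))
  d2 <- drop(sg_apply_matrix(y, params, spectrum$axis$step))
  out <- spectrum
  out$axis <- axis_from_values(spectrum$axis$values[idx])
  out$intensity <- -d2[idx]
  out
}

#' Estimate the noise standard deviation in a quiet region
#'
#' The sd of the residuals after removing a local linear trend in a region
#' free of analyte bands (default 1750--1800 cm^-1, above the amide I
#' envelope). The estimate is invariant to adding any linear function on the
#' region.
#'
#' @param spectrum A `sers_spectrum`.
#' @param quiet_region Wavenumber interval assumed band-free.
#' @param templates Optional template library; a warning is raised when a
#'   declared band center falls inside the quiet region.
#' @return An object of class `noise_estimate` with fields `sd`,
#'   `quiet_region` and `n_points`.
#' @export
estimate_noise_sd <- function(spectrum, quiet_region = c(1750, 1800),
                              templates = NULL) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  idx <- axis_which(spectrum$axis, quiet_region[1], quiet_region[2])
  if (length(idx) < 8)
    stop("quiet region holds ", length(idx), " points; at least 8 required")
  if (!is.null(templates)) {
    centers <- unlist(lapply(templates, function(tp)
      vapply(tp$bands, `[[`, 0, "center")))
    if (any(centers >= quiet_region[1] & centers <= quiet_region[2]))
      warning("quiet region overlaps a declared template band")
  }
  nu <- spectrum$axis$values[idx]
  y <- spectrum$intensity[idx]
  fit <- stats::lm.fit(cbind(1, nu - mean(nu)), y)
  r <- fit$residuals
  s <- sqrt(sum(r^2) / max(length(r) - 2, 1))
  structure(list(sd = s, quiet_region = quiet_region,
                 n_points = length(idx)), class = "noise_estimate")
}
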