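#' Construct a single spectrum
#'
#' A spectrum is one wavenumber-indexed intensity trace with acquisition
#' metadata. Intensities are in arbitrary units; no absolute calibration is
#' modelled.
#'
#' @param axis A [make_axis()] grid.
#' @param intensity Numeric vector, one value per grid point, all finite.
#' @param trap_state `"on"`, `"off"` or `NA` (trapping laser state).
#' @param session_id Free-text session identifier.
#' @param time_s Acquisition time stamp in seconds (may be `NA`).
#' @param integration_s Integration time in seconds, must be positive.
#' @param label_truth Optional ground-truth label attached by the simulator.
#' @return An object of class `sers_spectrum`.
#' @export
new_spectrum <- function(axis, intensity, trap_state = NA_character_,
                         session_id = "S1", time_s = NA_real_,
                         integration_s = 1, label_truth = NA_character_) {
  stopifnot(inherits(axis, "wn_axis"))
  if (length(intensity) != length(axis$values))
    stop("intensity length (", length(intensity),
         ") must equal axis length (", length(axis$values), ")")
  if (!all(is.finite(intensity))) stop("intensities must all be finite")
  if (!is.na(trap_state) && !trap_state %in% c("on", "off"))
    stop("trap_state must be \"on\", \"off\" or NA")
  if (!is.numeric(integration_s) || integration_s <= 0)
    stop("integration_s must be > 0")
  structure(
    list(axis = axis, intensity = as.numeric(intensity),
         meta = list(trap_state = trap_state, session_id = session_id,
                     time_s = time_s, integration_s = integration_s,
                     label_truth = label_truth)),
    class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf(
    "<sers_spectrum> %d points, %g..%g cm-1, trap %s, %g s integration\n",
    length(x$intensity), x$axis$values[1],
    x$axis$values[length(x$axis$values)],
    ifelse(is.na(x$meta$trap_state), "-", x$meta$trap_state),
    x$meta$integration_s))
  invisible(x)
}

#' Construct a spectrum set
#'
#' An ordered collection of spectra sharing one wavenumber axis, stored as a
#' points x spectra intensity matrix plus a per-spectrum metadata table.
#'
#' @param axis Shared [make_axis()] grid.
#' @param intensities Numeric matrix, `length(axis)` rows, one column per
#'   spectrum.
#' @param meta A `data.frame` with one row per spectrum (columns
#'   `trap_state`, `session_id`, `time_s`, `integration_s`, `label_truth`);
#'   defaults are filled in when omitted.
#' @return An object of class `sers_set`.
#' @export
new_spectrum_set <- function(axis, intensities, meta = NULL) {
  stopifnot(inherits(axis, "wn_axis"))
  intensities <- as.matrix(intensities)
  if (ncol(intensities) < 1) stop("a spectrum set must be non-empty")
  if (nrow(intensities) != length(axis$values))
    stop("intensity matrix must have one row per axis point")
  if (!all(is.finite(intensities))) stop("intensities must all be finite")
  n <- ncol(intensities)
  if (is.null(meta)) {
    meta <- data.frame(trap_state = NA_character_, session_id = "S1",
                       time_s = NA_real_, integration_s = 1,
                       label_truth = NA_character_,
                       stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (nrow(meta) != n) stop("meta must have one row per spectrum")
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "sers_set")
}

#' Number of spectra in a set
#' @param set A `sers_set`.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "sers_set"))
  ncol(set$intensities)
}

#' Extract one spectrum from a set
#' @param set A `sers_set`.
#' @param i Spectrum index.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "sers_set"), i >= 1, i <= n_spectra(set))
  m <- set$meta[i, ]
  new_spectrum(set$axis, set$intensities[, i], trap_state = m$trap_state,
               session_id = m$session_id, time_s = m$time_s,
               integration_s = m$integration_s, label_truth = m$label_truth)
}

#' Bundle spectra into a set
#'
#' All spectra must share the same axis; mixed axes are rejected rather than
#' silently resampled.
#' @param spectra List of `sers_spectrum` objects.
#' @export
as_spectrum_set <- function(spectra) {
  if (length(spectra) == 0) stop("a spectrum set must be non-empty")
  ax <- spectra[[1]]$axis
  ok <- vapply(spectra, function(s) axis_equal(s$axis, ax), logical(1))
  if (!all(ok))
    stop("spectra have mixed wavenumber axes; resample explicitly first")
  meta <- do.call(rbind, lapply(spectra, function(s)
    as.data.frame(s$meta, stringsAsFactors = FALSE)))
  new_spectrum_set(ax, vapply(spectra, function(s) s$intensity,
                              numeric(length(ax$values))), meta)
}

#' @export
print.sers_set <- function(x, ...) {
  cat(sprintf("<sers_set> %d spectra x %d points (%g..%g cm-1)\n",
              ncol(x$intensities), nrow(x$intensities),
              x$axis$values[1], x$axis$values[length(x$axis$values)]))
  invisible(x)
}

#' Linear resampling of a spectrum onto a new axis
#'
#' Linear interpolation; values at grid points shared by both axes are
#' unchanged. Extrapolation outside the source span is an error.
#'
#' @param spectrum A `sers_spectrum`.
#' @param axis Target [make_axis()] grid, fully inside the source span.
#' @export
resample <- function(spectrum, axis) {
  stopifnot(inherits(spectrum, "sers_spectrum"), inherits(axis, "wn_axis"))
  src <- spectrum$axis$values
  if (axis$values[1] < src[1] - 1e-9 ||
      axis$values[length(axis$values)] > src[length(src)] + 1e-9)
    stop("target axis extends outside the source span; refusing to extrapolate")
  y <- stats::approx(src, spectrum$intensity, xout = axis$values)$y
  out <- spectrum
  out$axis <- axis
  out$intensity <- y
  out
}
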