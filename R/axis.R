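#' Wavenumber axis
#'
#' A strictly ascending, uniformly spaced grid of Raman shifts (cm^-1). The
#' default 400--1800 cm^-1 span at 2 cm^-1 covers every marker band used by
#' the pipeline (490--1750 cm^-1) at the spectral resolution of the
#' spectrograph these analyses assume.
#'
#' @param start First grid point (cm^-1).
#' @param stop Upper bound (cm^-1); the last grid point is the largest
#'   `start + k*step` not exceeding `stop`.
#' @param step Grid spacing (cm^-1), must be positive.
#' @return An object of class `wn_axis` with fields `start`, `stop`, `step`
#'   and `values`.
#' @examples
#' ax <- make_axis(400, 1800, 2)
#' length(ax$values) # 701
#' @export
make_axis <- function(start = 400, stop = 1800, step = 2) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop("`step` must be a single positive number (got ", format(step), ")")
  if (!is.numeric(start) || !is.numeric(stop) || start >= stop)
    stop("`start` must be strictly below `stop` (start = ", format(start),
         ", stop = ", format(stop), ")")
  values <- seq(start, start + step * floor((stop - start) / step + 1e-9),
                by = step)
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "wn_axis")
}

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %g..%g cm-1, step %g (%d points)\n",
              x$values[1], x$values[length(x$values)], x$step,
              length(x$values)))
  invisible(x)
}

#' @export
length.wn_axis <- function(x) length(x$values)

axis_equal <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    max(abs(a$values - b$values)) <= tol
}

#' Indices of axis points falling inside a wavenumber interval
#' @keywords internal
axis_which <- function(axis, lo, hi) {
  if (lo < axis$values[1] - 1e-9 || hi > axis$values[length(axis$values)] + 1e-9)
    stop("region [", lo, ", ", hi, "] cm-1 lies outside the axis span [",
         axis$values[1], ", ", axis$values[length(axis$values)], "]")
  which(axis$values >= lo - 1e-9 & axis$values <= hi + 1e-9)
}

#' Rebuild a `wn_axis` object from raw grid values
#'
#' Validates strict ascent and uniform spacing.
#' @keywords internal
axis_from_values <- function(values, tol = 1e-6) {
  d <- diff(values)
  if (any(d <= 0)) stop("wavenumber axis must be strictly ascending")
  if (diff(range(d)) > tol * max(d)) stop("wavenumber axis must be uniform")
  make_axis(values[1], values[length(values)], stats::median(d))
}
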