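# Spectral grid containers: uniform chemical-shift axes with intensity
# arrays. These are the common currency of every operation in the package.

AXIS_TOL <- 1e-9

#' Default chemical-shift axis
#'
#' Uniform descending ppm axis covering the usual 1H biofluid window.
#' The default (9.995 to -0.005 ppm, 2^15 points, ~0.0003 ppm spacing)
#' matches typical processed 1D 1H resolution; coarser axes are fine for
#' quick work and are used throughout the test-suite.
#'
#' @param n number of grid points
#' @param from,to first (highest) and last (lowest) ppm value
#' @return numeric vector, strictly decreasing, uniform spacing
#' @export
default_ppm_axis <- function(n = 2^15, from = 9.995, to = -0.005) {
  stopifnot(n >= 2, from > to)
  seq(from, to, length.out = n)
}

axis_is_uniform <- function(x, tol = AXIS_TOL) {
  d <- diff(x)
  length(x) >= 2 && all(is.finite(x)) &&
    (all(d > 0) || all(d < 0)) &&
    max(abs(d - d[1])) < tol
}

axis_spacing <- function(x) abs(x[2] - x[1])

#' 1D spectrum on a uniform ppm grid
#'
#' @param ppm uniform, strictly monotone chemical-shift axis in ppm
#'   (conventionally descending)
#' @param intensity finite intensity per grid point (arbitrary units)
#' @return object of class `grid1d` with fields `ppm` and `intensity`
#' @export
spectrum_grid_1d <- function(ppm, intensity) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (!axis_is_uniform(ppm))
    stop("ppm axis must be strictly monotone with uniform spacing")
  if (length(intensity) != length(ppm))
    stop("intensity length (", length(intensity),
         ") does not match axis length (", length(ppm), ")")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  structure(list(ppm = ppm, intensity = intensity), class = "grid1d")
}

#' 2D spectrum (J-resolved or COSY) on uniform axes
#'
#' Intensity is stored as an f1 x f2 matrix: rows index the indirect (F1)
#' axis (Hz for J-Res, ppm for COSY), columns the chemical-shift (F2)
#' axis in ppm.
#'
#' @param f1 indirect axis (Hz for `mode = "jres"`, ppm for `"cosy"`)
#' @param f2 chemical-shift axis in ppm
#' @param intensity numeric matrix, `length(f1)` rows x `length(f2)` cols
#' @param mode `"jres"` or `"cosy"`
#' @return object of class `grid2d`
#' @export
spectrum_grid_2d <- function(f1, f2, intensity, mode = c("jres", "cosy")) {
  mode <- match.arg(mode)
  f1 <- as.numeric(f1); f2 <- as.numeric(f2)
  if (!axis_is_uniform(f1) || !axis_is_uniform(f2))
    stop("both axes must be strictly monotone with uniform spacing")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(f1) || ncol(intensity) != length(f2))
    stop("intensity matrix dimensions do not match axes")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  structure(list(f1 = f1, f2 = f2, intensity = intensity, mode = mode),
            class = "grid2d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> %d points, %.4f to %.4f ppm, max intensity %.4g\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              max(x$intensity)))
  invisible(x)
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d:%s> F1 %d x F2 %d, max intensity %.4g\n",
              x$mode, length(x$f1), length(x$f2), max(x$intensity)))
  invisible(x)
}

#' Trapezoidal integral of a 1D spectrum
#'
#' Integrates intensity over the ppm axis (direction-independent, so a
#' descending axis gives a positive area). An optional ppm window
#' restricts the integral to grid points inside `[lo, hi]`.
#'
#' @param spec a `grid1d`
#' @param window optional `c(lo, hi)` ppm window
#' @return scalar area in intensity x ppm units
#' @export
trapz_integral <- function(spec, window = NULL) {
  x <- spec$ppm; y <- spec$intensity
  if (!is.null(window)) {
    keep <- x >= min(window) & x <= max(window)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2) return(0)
  }
  sum((y[-1] + y[-length(y)]) / 2 * abs(diff(x)))
}

#' Resample a 1D spectrum onto a new uniform axis
#'
#' Linear interpolation; target points outside the source range are set
#' to zero. Non-negativity of the input is preserved (interpolation is a
#' convex combination).
#'
#' @param spec a `grid1d`
#' @param target_axis uniform monotone ppm axis to interpolate onto
#' @return `grid1d` on `target_axis`
#' @export
resample_to_grid <- function(spec, target_axis) {
  if (!axis_is_uniform(target_axis))
    stop("target axis must be uniform and strictly monotone")
  # approx() needs ascending x
  o <- order(spec$ppm)
  out <- stats::approx(spec$ppm[o], spec$intensity[o], xout = target_axis,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  spectrum_grid_1d(target_axis, out)
}

grids_equal <- function(a, b, tol = AXIS_TOL) {
  length(a) == length(b) && max(abs(a - b)) < tol
}
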