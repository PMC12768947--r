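#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on the spectrum's grid. The
#' defaults (window 5, degree 3) are the standard light smoothing applied to
#' every spectrum before modelling. Edge points are handled by the in-window
#' polynomial fit (no padding or wraparound), so polynomials up to `degree`
#' are exact fixed points of the filter, end to end.
#'
#' @param spectrum a [spectrum_1d()].
#' @param window odd filter span in grid points; must exceed `degree` and not
#'   exceed the number of grid points.
#' @param degree polynomial order of the local fit.
#'
#' @return A smoothed [spectrum_1d()] on the same grid.
#' @export
sg_smooth <- function(spectrum, window = 5L, degree = 3L) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L == 0L) stop("sg_smooth: window must be odd")
  if (window <= degree) stop("sg_smooth: window must exceed degree")
  if (window > spectrum$grid$n_points)
    stop("sg_smooth: window exceeds spectrum length")
  y <- signal::sgolayfilt(spectrum$intensities, p = degree, n = window)
  spectrum_1d(y, spectrum$grid, spectrum$label)
}

# largest odd integer <= n/3, at least `degree` + 2
default_baseline_window <- function(n_points, degree = 1L) {
  w <- floor(n_points / 3)
  if (w %% 2 == 0) w <- w - 1
  max(w, degree + 2 + (degree %% 2))
}

#' Baseline subtraction by wide Savitzky-Golay filtering
#'
#' Estimates the slowly varying background as a degree-1 (linear)
#' Savitzky-Golay filter over a wide window and subtracts it pointwise.
#' A window much wider than any Raman band (the default is about a third of
#' the spectrum) removes broad background humps while leaving narrow peaks
#' nearly intact; a pure linear ramp is removed exactly when the window spans
#' the spectrum.
#'
#' @param spectrum a [spectrum_1d()].
#' @param window odd baseline span in grid points; default about
#'   `n_points / 3`.
#' @param degree polynomial order of the baseline estimate (default 1).
#'
#' @return A baseline-subtracted [spectrum_1d()] on the same grid.
#' @export
subtract_baseline <- function(spectrum, window = NULL, degree = 1L) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  degree <- as.integer(degree)
  if (is.null(window))
    window <- default_baseline_window(spectrum$grid$n_points, degree)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("subtract_baseline: window must be odd")
  if (window <= degree) stop("subtract_baseline: window must exceed degree")
  if (window > spectrum$grid$n_points)
    stop("subtract_baseline: window exceeds spectrum length")
  baseline <- signal::sgolayfilt(spectrum$intensities, p = degree, n = window)
  spectrum_1d(spectrum$intensities - baseline, spectrum$grid, spectrum$label)
}

#' Normalize a spectrum to unit maximum
#'
#' Divides by the maximum intensity so the result peaks at exactly 1; the
#' original maximum is returned alongside (it is the quantity the
#' quantification chain multiplies back in, so `normalize` then `denormalize`
#' is the identity).
#'
#' @param spectrum a [spectrum_1d()] with at least one strictly positive
#'   intensity.
#'
#' @return A list with `spectrum` (unit-max [spectrum_1d()]) and `max_height`
#'   (the original maximum, arbitrary units).
#' @export
max_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  m <- max(spectrum$intensities)
  if (m <= 0)
    stop("max_normalize: spectrum has no strictly positive intensity")
  list(spectrum = spectrum_1d(spectrum$intensities / m, spectrum$grid,
                              spectrum$label),
       max_height = m)
}

#' Standard preprocessing chain
#'
#' Smooth, subtract baseline, and max-normalize, in that order — the chain
#' applied to a measured spectrum before it is compared with or fed to the
#' models.
#'
#' @inheritParams sg_smooth
#' @param baseline_window odd span for [subtract_baseline()]; `NULL` for the
#'   default wide window.
#' @param normalize if `FALSE`, skip the final unit-max normalization.
#'
#' @return As [max_normalize()] when `normalize = TRUE`, otherwise a
#'   [spectrum_1d()].
#' @export
preprocess_spectrum <- function(spectrum, window = 5L, degree = 3L,
                                baseline_window = NULL, normalize = TRUE) {
  out <- subtract_baseline(sg_smooth(spectrum, window, degree),
                           baseline_window)
  if (normalize) max_normalize(out) else out
}
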