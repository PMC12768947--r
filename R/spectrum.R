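#' Uniform wavenumber grid
#'
#' Constructs the wavenumber axis shared by every spectrum in an analysis.
#' All modelling in the package assumes a single uniform grid; the default
#' (400--2000 cm^-1, 660 points) brackets every PAH band the simulator uses,
#' including the pyrene marker at 1241 cm^-1 and the shared structure near
#' 1400 cm^-1.
#'
#' @param start first wavenumber (cm^-1).
#' @param end last wavenumber (cm^-1); must exceed `start`.
#' @param n_points number of uniformly spaced grid points (>= 2).
#'
#' @return An object of class `wavenumber_grid`: a list with `start`, `end`,
#'   `n_points` and the evaluated axis `wavenumbers`.
#' @export
#'
#' @examples
#' g <- wavenumber_grid()
#' g$n_points
wavenumber_grid <- function(start = 400, end = 2000, n_points = 660L) {
  if (!is.numeric(start) || !is.numeric(end) || start >= end)
    stop("wavenumber_grid: need start < end")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("wavenumber_grid: n_points must be >= 2")
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         n_points = n_points,
         wavenumbers = seq(as.numeric(start), as.numeric(end),
                           length.out = n_points)),
    class = "wavenumber_grid")
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g - %g cm^-1, %d points (spacing %.4g cm^-1)\n",
              x$start, x$end, x$n_points,
              (x$end - x$start) / (x$n_points - 1)))
  invisible(x)
}

grid_spacing <- function(grid) (grid$end - grid$start) / (grid$n_points - 1)

same_grid <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$start - b$start) < tol && abs(a$end - b$end) < tol
}

#' Spectrum on a fixed grid
#'
#' The atomic data unit: a vector of intensities (arbitrary units) on a
#' [wavenumber_grid()], plus a free-text label (a target name, `"blank"`, or
#' a sample id).
#'
#' @param intensities numeric vector, one finite value per grid point.
#' @param grid a [wavenumber_grid()].
#' @param label free-text identity.
#'
#' @return An object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(intensities, grid = wavenumber_grid(), label = "") {
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop(sprintf("spectrum_1d: %d intensities but grid has %d points",
                 length(intensities), grid$n_points))
  if (!all(is.finite(intensities)))
    stop("spectrum_1d: all intensities must be finite")
  structure(list(grid = grid, intensities = intensities,
                 label = as.character(label)),
            class = "spectrum_1d")
}

#' @export
print.spectrum_1d <- function(x, ...) {
  cat(sprintf("<spectrum_1d> '%s': %d points, %g - %g cm^-1, max %.4g at %.1f cm^-1\n",
              x$label, x$grid$n_points, x$grid$start, x$grid$end,
              max(x$intensities),
              x$grid$wavenumbers[which.max(x$intensities)]))
  invisible(x)
}

#' @export
plot.spectrum_1d <- function(x, ..., xlab = expression(Wavenumber ~ (cm^-1)),
                             ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$grid$wavenumbers, x$intensities, type = type,
                 xlab = xlab, ylab = ylab, main = x$label, ...)
  invisible(x)
}

#' Ordered collection of spectra on one shared grid
#'
#' @param spectra list of [spectrum_1d()] objects sharing an identical grid.
#' @param role one of `"reference"`, `"blank"`, `"train"`, `"validation"`,
#'   `"optimization"`, `"test"`.
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, role = c("reference", "blank", "train",
                                           "validation", "optimization",
                                           "test")) {
  role <- match.arg(role)
  if (!length(spectra)) stop("spectrum_set: empty collection")
  g <- spectra[[1L]]$grid
  ok <- vapply(spectra, function(s) inherits(s, "spectrum_1d") &&
                 same_grid(s$grid, g), logical(1))
  if (!all(ok)) stop("spectrum_set: all members must be spectrum_1d on one grid")
  names(spectra) <- vapply(spectra, `[[`, character(1), "label")
  structure(list(spectra = spectra, role = role, grid = g),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> role '%s': %d spectra [%s] on %d-point grid\n",
              x$role, length(x$spectra),
              paste(names(x$spectra), collapse = ", "), x$grid$n_points))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

# intensities of a spectrum_set as an n x w matrix (rows = spectra)
set_matrix <- function(set) {
  do.call(rbind, lapply(set$spectra, `[[`, "intensities"))
}
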