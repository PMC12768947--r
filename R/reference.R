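#' @name reference
#' @title Synthetic PAH reference library
#'
#' @description
#' The five PAH targets analysed throughout the package are pyrene (PY),
#' triphenylene (TP), nitro-pyrene (NP), benzo[a]pyrene (BAP) and anthracene
#' (ANT). Because no measured SERS library is distributed, the package ships
#' a synthetic stand-in built from Lorentzian bands that reproduces the
#' qualitative structure of the real spectra: PY's dominant ring-stretch band
#' at 1241 cm^-1, ANT with exactly three bands, BAP with eight, NP with no
#' unique bands (each NP band overlaps another target's), and PY/NP/ANT all
#' sharing structure near 1240 and 1400 cm^-1.
NULL

PAH_TARGETS <- c("PY", "TP", "NP", "BAP", "ANT")

#' Single Lorentzian band specification
#'
#' @param center band center (cm^-1), inside the working grid.
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param rel_height apex height relative to the reference maximum, in (0, 1].
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, fwhm = 12, rel_height = 1) {
  if (fwhm <= 0) stop("peak_spec: fwhm must be positive")
  if (rel_height <= 0 || rel_height > 1)
    stop("peak_spec: rel_height must be in (0, 1]")
  structure(list(center = center, fwhm = fwhm, rel_height = rel_height),
            class = "peak_spec")
}

#' Reference definition: a named target and its band table
#'
#' @param target one of `PY`, `TP`, `NP`, `BAP`, `ANT` (other names allowed
#'   for custom libraries).
#' @param peaks list of [peak_spec()]; exactly one must have
#'   `rel_height = 1`.
#' @return A `reference_definition` list.
#' @export
reference_definition <- function(target, peaks) {
  if (!length(peaks)) stop("reference_definition: need at least one peak")
  n_unit <- sum(vapply(peaks, function(p) p$rel_height, numeric(1)) == 1)
  if (n_unit != 1L)
    stop("reference_definition: exactly one peak must have rel_height = 1")
  structure(list(target = target, peaks = peaks),
            class = "reference_definition")
}

# sum of Lorentzians evaluated on a wavenumber axis
lorentzian_sum <- function(wn, peaks) {
  y <- numeric(length(wn))
  for (p in peaks) {
    gamma <- p$fwhm / 2
    y <- y + p$rel_height * gamma^2 / (gamma^2 + (wn - p$center)^2)
  }
  y
}

#' Build one unit-max reference spectrum from its band table
#'
#' Evaluates the sum of Lorentzian bands on the grid and normalizes to unit
#' maximum.
#'
#' @param defn a [reference_definition()].
#' @param grid a [wavenumber_grid()].
#' @return A unit-max [spectrum_1d()] labelled with the target name.
#' @export
make_reference <- function(defn, grid = wavenumber_grid()) {
  stopifnot(inherits(defn, "reference_definition"))
  centers <- vapply(defn$peaks, function(p) p$center, numeric(1))
  if (any(centers < grid$start | centers > grid$end))
    stop("make_reference: peak center outside grid for ", defn$target)
  y <- lorentzian_sum(grid$wavenumbers, defn$peaks)
  spectrum_1d(y / max(y), grid, defn$target)
}

# Band tables for the five synthetic references. Constraints honoured:
#   ANT has exactly 3 bands, BAP exactly 8; every NP center lies within one
#   FWHM of some other target's center; PY, NP and ANT each have a band
#   within 10 cm^-1 of both 1240 and 1400 cm^-1; PY's dominant band is at
#   1241 cm^-1.
default_reference_definitions <- function(fwhm = 12) {
  pk <- function(center, rel) peak_spec(center, fwhm, rel)
  list(
    PY  = reference_definition("PY", list(
      pk(1241, 1.00), pk(1400, 0.60), pk(590, 0.35), pk(1065, 0.45),
      pk(1625, 0.30))),
    TP  = reference_definition("TP", list(
      pk(698, 0.70), pk(1060, 1.00), pk(1340, 0.50), pk(1458, 0.60),
      pk(1600, 0.40))),
    NP  = reference_definition("NP", list(
      pk(1243, 0.90), pk(1399, 1.00), pk(1337, 0.50), pk(1512, 0.45),
      pk(755, 0.60))),
    BAP = reference_definition("BAP", list(
      pk(611, 0.50), pk(774, 0.60), pk(955, 0.45), pk(1135, 0.55),
      pk(1352, 1.00), pk(1512, 0.40), pk(1635, 0.35), pk(1760, 0.30))),
    ANT = reference_definition("ANT", list(
      pk(1403, 1.00), pk(1247, 0.55), pk(754, 0.40)))
  )
}

#' Default five-target synthetic reference library
#'
#' @param grid a [wavenumber_grid()].
#' @param fwhm Lorentzian full width at half maximum shared by all bands
#'   (cm^-1).
#' @return A [spectrum_set()] with role `"reference"` holding the five
#'   unit-max references in the order PY, TP, NP, BAP, ANT.
#' @export
default_reference_library <- function(grid = wavenumber_grid(), fwhm = 12) {
  defs <- default_reference_definitions(fwhm)
  spectrum_set(lapply(defs, make_reference, grid = grid), role = "reference")
}

#' Count resolvable peaks in a spectrum
#'
#' Local maxima whose height exceeds `frac` of the spectrum maximum; used to
#' audit the reference library (ANT must show 3, BAP 8).
#'
#' @param spectrum a [spectrum_1d()].
#' @param frac height threshold as a fraction of the maximum.
#' @return Integer vector of grid indices of the qualifying local maxima.
#' @export
find_peaks <- function(spectrum, frac = 0.1) {
  y <- spectrum$intensities
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i[y[i] > frac * max(y)]
}

#' Noise and augmentation configuration
#'
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   spectrum maximum.
#' @param max_shift largest random spectral shift, in grid points.
#' @param background_scale blank background amplitude as a fraction of unit
#'   reference maximum.
#' @param seed integer seed, or `NA` to use the current RNG state.
#' @return A `noise_config` list.
#' @export
noise_config <- function(noise_sd = 0.01, max_shift = 2L,
                         background_scale = 0.1, seed = NA_integer_) {
  if (noise_sd < 0 || max_shift < 0 || background_scale < 0)
    stop("noise_config: all magnitudes must be nonnegative")
  structure(list(noise_sd = noise_sd, max_shift = as.integer(max_shift),
                 background_scale = background_scale, seed = seed),
            class = "noise_config")
}

# smooth low-order polynomial background profile on [0, 1], unit max
background_profile <- function(t, profile = c("drinking", "river")) {
  profile <- match.arg(profile)
  h <- if (profile == "drinking") {
    0.75 * 4 * t * (1 - t) + 0.25 * (1 - t)
  } else {
    # river water: broader hump with a stronger low-wavenumber rise
    0.55 * 4 * t * (1 - t) + 0.45 * (1 - t)^2 + 0.15 * t * (1 - t)^2
  }
  h / max(h)
}

#' Simulated water-blank background spectrum
#'
#' A smooth, broad polynomial hump (the SERS background of the water matrix)
#' scaled by `cfg$background_scale`, plus Gaussian noise of sd
#' `cfg$noise_sd`. Deterministic when `cfg$seed` is set.
#'
#' @param grid a [wavenumber_grid()].
#' @param cfg a [noise_config()].
#' @param profile `"drinking"` (tap water) or `"river"` (broader, stronger
#'   background).
#' @return A [spectrum_1d()] labelled `"blank"`.
#' @export
make_blank <- function(grid = wavenumber_grid(), cfg = noise_config(),
                       profile = c("drinking", "river")) {
  profile <- match.arg(profile)
  if (!is.na(cfg$seed)) set.seed(cfg$seed)
  t <- (grid$wavenumbers - grid$start) / (grid$end - grid$start)
  y <- cfg$background_scale * background_profile(t, profile)
  if (cfg$noise_sd > 0)
    y <- y + stats::rnorm(grid$n_points, 0, cfg$noise_sd)
  spectrum_1d(y, grid, "blank")
}

#' Saturating (Hill/Langmuir) concentration-response model
#'
#' Characteristic peak height as a function of concentration:
#' `h(c) = h_max * c / (K + c)` — zero at zero, strictly increasing,
#' saturating at `h_max`, invertible on (0, h_max).
#'
#' @param target target name.
#' @param h_max saturation height (arbitrary units), > 0.
#' @param K concentration at half saturation (uM), > 0.
#' @return A `response_model` list.
#' @export
response_model <- function(target, h_max, K) {
  if (h_max <= 0 || K <= 0) stop("response_model: h_max and K must be > 0")
  structure(list(target = target, h_max = h_max, K = K),
            class = "response_model")
}

#' Evaluate a response model
#' @param model a [response_model()].
#' @param conc concentration(s), uM, >= 0.
#' @return Peak height(s), arbitrary units.
#' @export
response_height <- function(model, conc) {
  if (any(conc < 0)) stop("response_height: concentrations must be >= 0")
  model$h_max * conc / (model$K + conc)
}

#' Default per-target response models
#'
#' Half-saturation at 0.35 uM puts the 10 nM - 1 uM calibration range at
#' roughly 3%-74% of saturation. ANT is given the lowest saturation height,
#' mirroring its weakest SERS response among the five targets.
#'
#' @return Named list of [response_model()], in PY, TP, NP, BAP, ANT order.
#' @export
default_response_models <- function() {
  h <- c(PY = 1.0, TP = 0.9, NP = 0.8, BAP = 0.85, ANT = 0.5)
  out <- lapply(PAH_TARGETS, function(t) response_model(t, h[[t]], 0.35))
  names(out) <- PAH_TARGETS
  out
}

#' Split a total concentration by a mixing ratio
#'
#' @param total total concentration (uM), >= 0.
#' @param ratio nonnegative 5-vector of mixing weights with at least one
#'   positive entry.
#' @return 5-vector of concentrations summing exactly to `total`.
#' @export
#'
#' @examples
#' ratio_to_concentrations(1, c(5, 2, 1, 1, 1))  # 0.5 0.2 0.1 0.1 0.1
ratio_to_concentrations <- function(total, ratio) {
  if (total < 0) stop("ratio_to_concentrations: total must be >= 0")
  if (any(ratio < 0) || all(ratio == 0))
    stop("ratio_to_concentrations: ratio must be nonnegative with a positive entry")
  total * ratio / sum(ratio)
}

#' Simulate a measured mixture spectrum at known concentrations
#'
#' Raw-scale forward model of a "measured" sample: each target contributes
#' its unit-max reference scaled by the response-model height at its
#' concentration; the blank background and Gaussian noise are added on top.
#' The raw (unnormalized) scale is retained.
#'
#' @param concs named or ordered concentration vector (uM) over the library
#'   targets, all >= 0.
#' @param responses named list of [response_model()] per target.
#' @param refs reference [spectrum_set()] (unit-max spectra).
#' @param cfg a [noise_config()]; `background_scale` controls the blank
#'   amplitude, `noise_sd` the noise (as a fraction of the signal maximum).
#' @param profile background profile passed to [make_blank()].
#' @return A [spectrum_1d()] on the raw scale, labelled `"measured"`.
#' @export
simulate_measured_spectrum <- function(concs, responses, refs,
                                       cfg = noise_config(),
                                       profile = c("drinking", "river")) {
  profile <- match.arg(profile)
  targets <- names(refs$spectra)
  if (!is.null(names(concs))) concs <- concs[targets]
  if (length(concs) != length(targets) || any(is.na(concs)))
    stop("simulate_measured_spectrum: need one concentration per reference")
  if (any(concs < 0))
    stop("simulate_measured_spectrum: concentrations must be >= 0")
  heights <- vapply(seq_along(targets), function(i)
    response_height(responses[[targets[i]]], concs[i]), numeric(1))
  y <- numeric(refs$grid$n_points)
  for (i in seq_along(targets))
    y <- y + heights[i] * refs$spectra[[i]]$intensities
  bg <- make_blank(refs$grid, noise_config(0, 0, cfg$background_scale), profile)
  y <- y + bg$intensities
  if (cfg$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd * max(max(y), 1e-12))
  spectrum_1d(y, refs$grid, "measured")
}
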