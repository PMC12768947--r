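#' Draw one contribution-label vector
#'
#' Each of the five targets is independently zeroed with probability
#' `zero_prob`; the survivors receive positive fractions normalized to sum
#' to 1, redrawn until every nonzero fraction is at least `min_frac` of the
#' total. If all five are zeroed the all-zero vector is returned (a blank
#' sample). Uses the current RNG state.
#'
#' @param zero_prob per-target zeroing probability (default 0.2).
#' @param min_frac minimum nonzero fractional contribution (default 0.01).
#' @return Numeric 5-vector: zeros plus positive fractions summing to 1
#'   (or all zeros).
#' @export
sample_contributions <- function(zero_prob = 0.2, min_frac = 0.01) {
  if (zero_prob < 0 || zero_prob > 1)
    stop("sample_contributions: zero_prob must be in [0, 1]")
  if (min_frac <= 0 || min_frac * 5 >= 1)
    stop("sample_contributions: infeasible min_frac (need 0 < 5*min_frac < 1)")
  keep <- stats::runif(5L) >= zero_prob
  out <- numeric(5L)
  k <- sum(keep)
  if (k == 0L) return(out)
  repeat {
    u <- stats::runif(k)
    f <- u / sum(u)
    if (all(f >= min_frac)) break
  }
  out[keep] <- f
  out
}

#' Shift a spectrum by a random integer offset
#'
#' Translates the intensity vector by an offset drawn uniformly from
#' `[-max_shift, +max_shift]` grid points (emulating instrument wavenumber
#' jitter); vacated edge points are filled by edge-value extension and the
#' grid is unchanged.
#'
#' @param spectrum a [spectrum_1d()].
#' @param max_shift largest offset magnitude in grid points.
#' @return A shifted [spectrum_1d()].
#' @export
apply_random_shift <- function(spectrum, max_shift = 2L) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  max_shift <- as.integer(max_shift)
  if (max_shift < 0) stop("apply_random_shift: max_shift must be >= 0")
  if (max_shift == 0L) return(spectrum)
  s <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
  spectrum_1d(shift_intensities(spectrum$intensities, s), spectrum$grid,
              spectrum$label)
}

# translate by s points with edge-value extension
shift_intensities <- function(y, s) {
  n <- length(y)
  if (s == 0) return(y)
  if (s > 0) c(rep(y[1L], s), y[1:(n - s)])
  else c(y[(1 - s):n], rep(y[n], -s))
}

#' Compose one labelled training mixture
#'
#' Scaled addition of the unit-max references: raw mixture
#' `M = sum(a_i * R_i) + blank + noise` with `a_i = contributions_i * S` for
#' a total-signal scale `S` drawn log-uniformly over `scale_range`. The
#' stored sample is `M / max(M)` together with the 6-number regression label
#' (the five fractional contributions and the normalization factor
#' `z = max(M) / S`), chosen so that `(l_i / z) * max(M) = a_i`: dividing a
#' contribution by z and scaling by the raw maximum recovers that target's
#' absolute signal height.
#'
#' @param contributions 5-vector from [sample_contributions()].
#' @param refs reference [spectrum_set()] (unit-max).
#' @param blank smooth background [spectrum_1d()] (noise-free).
#' @param cfg a [noise_config()] providing `noise_sd` and `max_shift`.
#' @param scale_range range of the log-uniform total-signal scale S.
#' @param scale fixed total-signal scale S; overrides `scale_range` when
#'   given (used to build samples whose absolute heights are known).
#' @return A `training_sample` list: `spectrum` (unit-max [spectrum_1d()]),
#'   `presence`, `contributions`, `norm_factor`, `raw_max`, `scale`.
#' @export
compose_mixture <- function(contributions, refs, blank,
                            cfg = noise_config(), scale_range = c(0.1, 10),
                            scale = NULL) {
  if (length(contributions) != length(refs$spectra))
    stop("compose_mixture: one contribution per reference required")
  S <- if (is.null(scale))
    exp(stats::runif(1L, log(scale_range[1L]), log(scale_range[2L])))
  else scale
  a <- contributions * S
  y <- blank$intensities
  for (i in seq_along(a))
    if (a[i] > 0) y <- y + a[i] * refs$spectra[[i]]$intensities
  if (cfg$max_shift > 0L) {
    s <- sample.int(2L * cfg$max_shift + 1L, 1L) - cfg$max_shift - 1L
    y <- shift_intensities(y, s)
  }
  if (cfg$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd * max(max(y), 1e-12))
  raw_max <- max(y)
  if (raw_max <= 0)
    stop("compose_mixture: degenerate sample (no signal and no background)")
  any_target <- any(contributions > 0)
  structure(list(
    spectrum = spectrum_1d(y / raw_max, refs$grid, "mixture"),
    presence = as.integer(contributions > 0),
    contributions = contributions,
    norm_factor = if (any_target) raw_max / S else 1,
    raw_max = raw_max,
    scale = S), class = "training_sample")
}

#' Generate a labelled simulated dataset
#'
#' Fabricates `n` independent training samples by the full procedure:
#' contribution sampling (20% zeroing, 1% floor), scaled addition of the
#' references over the blank background, random shift, Gaussian noise, and
#' unit-max normalization. Fully reproducible from `seed`.
#'
#' @param n number of samples; role defaults are 10000 (train),
#'   2000 (validation), 6000 (optimization).
#' @param role `"train"`, `"validation"` or `"optimization"`.
#' @param refs reference [spectrum_set()] from
#'   [default_reference_library()].
#' @param cfg a [noise_config()].
#' @param seed integer seed.
#' @param zero_prob,min_frac label rules, see [sample_contributions()].
#' @param scale_range total-signal scale range, see [compose_mixture()].
#' @param profile background profile, see [make_blank()].
#' @return A `sim_dataset`: intensity matrix `x` (n rows, one per sample),
#'   `presence` and `contributions` (n x 5), `norm_factor` and `raw_max`
#'   (length n), the grid, role, seed and a config snapshot.
#' @export
generate_dataset <- function(n, role = c("train", "validation",
                                         "optimization", "test"),
                             refs = default_reference_library(),
                             cfg = noise_config(), seed = 1L,
                             zero_prob = 0.2, min_frac = 0.01,
                             scale_range = c(0.1, 10),
                             profile = c("drinking", "river")) {
  role <- match.arg(role)
  profile <- match.arg(profile)
  if (n < 1L) stop("generate_dataset: n must be >= 1")
  set.seed(seed)
  blank <- make_blank(refs$grid,
                      noise_config(0, 0, cfg$background_scale), profile)
  w <- refs$grid$n_points
  x <- matrix(0, n, w)
  presence <- matrix(0L, n, length(refs$spectra))
  contributions <- matrix(0, n, length(refs$spectra))
  norm_factor <- numeric(n)
  raw_max <- numeric(n)
  for (i in seq_len(n)) {
    ctr <- sample_contributions(zero_prob, min_frac)
    smp <- compose_mixture(ctr, refs, blank, cfg, scale_range)
    x[i, ] <- smp$spectrum$intensities
    presence[i, ] <- smp$presence
    contributions[i, ] <- smp$contributions
    norm_factor[i] <- smp$norm_factor
    raw_max[i] <- smp$raw_max
  }
  colnames(presence) <- colnames(contributions) <- names(refs$spectra)
  structure(list(
    x = x, presence = presence, contributions = contributions,
    norm_factor = norm_factor, raw_max = raw_max,
    grid = refs$grid, role = role, seed = seed,
    config = list(noise = unclass(cfg), zero_prob = zero_prob,
                  min_frac = min_frac, scale_range = scale_range,
                  profile = profile, n = n)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> role '%s': %d samples x %d points, seed %d\n",
              x$role, nrow(x$x), ncol(x$x), x$seed))
  cat(sprintf("  per-target zero rate: %s\n",
              paste(sprintf("%.3f", colMeans(x$contributions == 0)),
                    collapse = " ")))
  invisible(x)
}
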