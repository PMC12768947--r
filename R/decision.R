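#' Geometric-mean threshold selection
#'
#' Chooses the decision threshold for one target by maximizing the geometric
#' mean of sensitivity and specificity, `sqrt(sens * spec)`, over candidate
#' thresholds placed at midpoints between adjacent sorted unique scores
#' (plus the all-positive and all-negative extremes). A score exactly equal
#' to the threshold is called positive. Ties in the geometric mean are
#' broken toward the lowest threshold.
#'
#' @param scores numeric vector of classifier scores in `[0, 1]`.
#' @param truth binary vector (0/1) of the same length, containing at least
#'   one positive and one negative.
#' @return A list with `threshold` and `geometric_mean`.
#' @export
choose_threshold <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop("choose_threshold: scores and truth lengths differ")
  if (all(truth == 1L) || all(truth == 0L))
    stop("choose_threshold: truth must contain both classes")
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1e-6,
            if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1e-6)
  npos <- sum(truth == 1L)
  nneg <- sum(truth == 0L)
  best_gm <- -1; best_thr <- cand[1L]
  for (thr in cand) {
    call <- scores >= thr
    sens <- sum(call & truth == 1L) / npos
    spec <- sum(!call & truth == 0L) / nneg
    gm <- sqrt(sens * spec)
    if (gm > best_gm + 1e-12) { best_gm <- gm; best_thr <- thr }
  }
  list(threshold = best_thr, geometric_mean = best_gm)
}

#' Fit per-target thresholds on validation scores
#'
#' @param scores `n x 5` classifier score matrix (validation set).
#' @param truth `n x 5` binary presence matrix.
#' @return An object of class `threshold_set`: per-target thresholds and
#'   achieved geometric means.
#' @export
fit_thresholds <- function(scores, truth) {
  stopifnot(ncol(scores) == ncol(truth), nrow(scores) == nrow(truth))
  fits <- lapply(seq_len(ncol(scores)), function(j)
    choose_threshold(scores[, j], truth[, j]))
  structure(list(
    thresholds = vapply(fits, `[[`, numeric(1), "threshold"),
    geometric_means = vapply(fits, `[[`, numeric(1), "geometric_mean"),
    targets = colnames(truth)), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  tab <- rbind(threshold = x$thresholds, geometric_mean = x$geometric_means)
  colnames(tab) <- if (!is.null(x$targets)) x$targets else
    paste0("T", seq_along(x$thresholds))
  print(round(tab, 4))
  invisible(x)
}

#' Apply thresholds to a score matrix
#'
#' @param scores `n x 5` score matrix.
#' @param thresholds a [fit_thresholds()] object (or numeric vector).
#' @return `n x 5` binary matrix; `score >= threshold` calls positive.
#' @export
classify <- function(scores, thresholds) {
  thr <- if (inherits(thresholds, "threshold_set")) thresholds$thresholds
         else thresholds
  if (ncol(scores) != length(thr))
    stop("classify: one threshold per score column required")
  out <- matrix(0L, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
  for (j in seq_along(thr)) out[, j] <- as.integer(scores[, j] >= thr[j])
  out
}

#' Fit a monotone calibration curve
#'
#' Fits the relation between analyte concentration and characteristic SERS
#' peak height. The default `"hill"` form `h = h_max * c / (K + c)` is
#' monotone and closed-form invertible; `"poly_log"` fits a quadratic in
#' `log10(c)` (mirroring a polynomial calibration) and is accepted only if
#' it is strictly increasing over the data range.
#'
#' @param concs concentrations (uM), at least 4 distinct positive values.
#' @param heights peak heights (arbitrary units), positive.
#' @param form `"hill"` or `"poly_log"`.
#' @return An object of class `calibration_curve` with `predict` (conc ->
#'   height) and [inverse_calibration()] (height -> conc) support.
#' @export
fit_calibration_curve <- function(concs, heights, form = c("hill", "poly_log")) {
  form <- match.arg(form)
  if (length(unique(concs)) < 4L)
    stop("fit_calibration_curve: need at least 4 distinct concentrations")
  if (length(concs) != length(heights))
    stop("fit_calibration_curve: concs and heights lengths differ")
  if (any(heights <= 0)) stop("fit_calibration_curve: heights must be positive")
  rng <- range(concs)
  if (form == "hill") {
    start <- list(h_max = max(heights) * 1.2,
                  K = stats::median(concs))
    fit <- tryCatch(
      minpack.lm::nlsLM(heights ~ h_max * concs / (K + concs),
                        start = start,
                        lower = c(h_max = 1e-12, K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("fit_calibration_curve: Hill fit failed (", conditionMessage(e),
             "); data may not follow a monotone saturating form",
             call. = FALSE))
    pars <- stats::coef(fit)
    obj <- list(form = "hill", h_max = unname(pars["h_max"]),
                K = unname(pars["K"]), range = rng)
  } else {
    lx <- log10(concs)
    fit <- stats::lm(heights ~ lx + I(lx^2))
    cf <- unname(stats::coef(fit))
    # monotone over the data range: derivative b1 + 2 b2 * lx > 0 at both ends
    d <- cf[2L] + 2 * cf[3L] * range(lx)
    if (any(d <= 0))
      stop("fit_calibration_curve: poly_log fit is not monotone over the data range")
    obj <- list(form = "poly_log", coef = cf, range = rng)
  }
  resid_rel <- (predict_height(obj, concs) - heights) / max(heights)
  if (max(abs(resid_rel)) > 0.25)
    stop("fit_calibration_curve: poor fit (max relative residual ",
         sprintf("%.2f", max(abs(resid_rel))),
         "); data may not follow the chosen monotone form")
  obj$rmse <- sqrt(mean((predict_height(obj, concs) - heights)^2))
  class(obj) <- "calibration_curve"
  obj
}

# forward map concentration -> height for a calibration curve (or a
# response_model, which shares the hill algebra)
predict_height <- function(curve, conc) {
  if (inherits(curve, "response_model"))
    return(response_height(curve, conc))
  if (curve$form == "hill") curve$h_max * conc / (curve$K + conc)
  else {
    lx <- log10(pmax(conc, 1e-300))
    curve$coef[1L] + curve$coef[2L] * lx + curve$coef[3L] * lx^2
  }
}

#' @export
predict.calibration_curve <- function(object, conc, ...) {
  predict_height(object, conc)
}

#' Invert a calibration curve: height to concentration
#'
#' Closed form for the Hill form; monotone root finding for `poly_log`.
#' Heights at or below the curve's value at zero concentration map to 0;
#' heights above the calibrated range are extrapolated and flagged.
#'
#' @param curve a [fit_calibration_curve()] object.
#' @param height peak height(s).
#' @return Numeric vector of concentrations (uM), with attribute
#'   `"extrapolated"` marking values outside the calibrated range.
#' @export
inverse_calibration <- function(curve, height) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- vapply(height, function(h) {
    if (h <= 0) return(0)
    if (curve$form == "hill") {
      if (h >= curve$h_max) return(100 * curve$range[2L])  # beyond saturation
      curve$K * h / (curve$h_max - h)
    } else {
      lo <- log10(curve$range[1L]) - 3
      hi <- log10(curve$range[2L]) + 2
      f <- function(lx) curve$coef[1L] + curve$coef[2L] * lx +
        curve$coef[3L] * lx^2 - h
      if (f(lo) >= 0) return(0)
      if (f(hi) <= 0) return(10^hi)
      10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    }
  }, numeric(1))
  attr(conc, "extrapolated") <- conc > curve$range[2L] | conc < curve$range[1L]
  conc
}

#' @export
print.calibration_curve <- function(x, ...) {
  if (x$form == "hill")
    cat(sprintf("<calibration_curve> hill: h_max %.4g, K %.4g uM, range %.3g - %.3g uM\n",
                x$h_max, x$K, x$range[1L], x$range[2L]))
  else
    cat(sprintf("<calibration_curve> poly_log: coef (%s), range %.3g - %.3g uM\n",
                paste(sprintf("%.4g", x$coef), collapse = ", "),
                x$range[1L], x$range[2L]))
  invisible(x)
}

#' Limit of detection from a calibration curve
#'
#' Smallest concentration whose predicted peak height reaches
#' `snr * blank_sd` — the signal-to-noise criterion (default S/N = 3.5).
#'
#' @param curve a [fit_calibration_curve()] object.
#' @param blank_sd standard deviation of the blank signal at the
#'   characteristic band (same units as heights).
#' @param snr required signal-to-noise ratio.
#' @return The LOD (uM), with attribute `"below_range"` if it falls under
#'   the calibrated range.
#' @export
estimate_lod <- function(curve, blank_sd, snr = 3.5) {
  if (blank_sd <= 0) stop("estimate_lod: blank_sd must be positive")
  if (snr < 0) stop("estimate_lod: snr must be >= 0")
  target <- snr * blank_sd
  if (target == 0) {
    lod <- 0
  } else {
    hmax <- if (curve$form == "hill") curve$h_max else
      predict_height(curve, 10 * curve$range[2L])
    if (target >= hmax)
      stop("estimate_lod: required signal exceeds the curve maximum; not detectable")
    lod <- unname(inverse_calibration(curve, target))
    attributes(lod) <- NULL
  }
  attr(lod, "below_range") <- lod < curve$range[1L]
  lod
}

#' Convert regressor outputs to concentrations
#'
#' Implements the conversion chain: each predicted contribution is divided
#' by the predicted normalization factor, scaled by the raw (unnormalized)
#' maximum of the test spectrum to give an absolute peak height, and pushed
#' through the target's calibration-curve inverse — with a hard floor of 0
#' (negative contributions and sub-blank heights report zero concentration).
#'
#' @param pred 6-vector `(l1..l5, z)` from the regressor.
#' @param raw_max maximum of the unnormalized test spectrum (> 0).
#' @param curves named list of [fit_calibration_curve()] per target.
#' @param z_floor smallest admissible normalization factor; predictions at
#'   or below it are a degenerate-normalization error.
#' @return An object of class `quant_result`: per-target `concentrations`
#'   (uM, all >= 0), `heights`, and `extrapolated` flags.
#' @export
contributions_to_concentrations <- function(pred, raw_max, curves,
                                            z_floor = 1e-6) {
  if (length(pred) != length(curves) + 1L)
    stop("contributions_to_concentrations: need 5 contributions plus z")
  if (raw_max <= 0)
    stop("contributions_to_concentrations: raw_max must be positive")
  z <- pred[length(pred)]
  if (z <= z_floor)
    stop("contributions_to_concentrations: degenerate normalization factor")
  l <- pmax(pred[-length(pred)], 0)
  heights <- l / z * raw_max
  conc <- numeric(length(heights))
  extra <- logical(length(heights))
  for (i in seq_along(heights)) {
    ci <- inverse_calibration(curves[[i]], heights[i])
    conc[i] <- max(ci, 0)
    extra[i] <- attr(ci, "extrapolated")[1L]
  }
  names(conc) <- names(curves)
  structure(list(concentrations = conc, heights = heights,
                 extrapolated = extra), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> concentrations (uM):\n")
  print(round(x$concentrations, 4))
  if (any(x$extrapolated))
    cat("  (", sum(x$extrapolated), "value(s) outside the calibrated range)\n")
  invisible(x)
}
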