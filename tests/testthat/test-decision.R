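test_that("geometric-mean threshold separates separable scores perfectly", {
  r <- choose_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$geometric_mean, 1.0)
  expect_gt(r$threshold, 0.2)
  expect_lte(r$threshold, 0.8)
  expect_error(choose_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("threshold choice equals brute-force search on random instances", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(4:100, 1)
    scores <- round(runif(n), 2)  # force score ties
    truth <- rbinom(n, 1, 0.5)
    if (all(truth == 1) || all(truth == 0)) next
    got <- choose_threshold(scores, truth)
    expect_equal(got$geometric_mean, brute_force_gm(scores, truth),
                 tolerance = 1e-12)
  }
  # all-identical scores: forced all-positive or all-negative call
  r <- choose_threshold(rep(0.5, 6), c(1, 1, 1, 1, 0, 0))
  expect_equal(r$geometric_mean, brute_force_gm(rep(0.5, 6),
                                                c(1, 1, 1, 1, 0, 0)))
})

test_that("classification uses the score >= threshold convention", {
  thr <- structure(list(thresholds = c(0.5, 0.5, 0.5, 0.5, 0.5)),
                   class = "threshold_set")
  sc <- matrix(c(0.5, 0.49, 0, 1, 0.51), 1)
  expect_identical(as.vector(classify(sc, thr)), c(1L, 0L, 0L, 1L, 1L))
  z <- matrix(0, 4, 5)
  expect_true(all(classify(z, thr) == 0L))
  set.seed(15)
  sc <- matrix(runif(200), 40)
  thrv <- runif(5)
  got <- classify(sc, thrv)
  expect_identical(got, matrix(as.integer(sweep(sc, 2, thrv, `>=`)), 40))
})

test_that("Hill calibration refits its own data and inverts exactly", {
  concs <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)
  h <- 1.2 * concs / (0.3 + concs)
  curve <- fit_calibration_curve(concs, h)
  expect_equal(curve$h_max, 1.2, tolerance = 0.01)
  expect_equal(curve$K, 0.3, tolerance = 0.01)
  probes <- seq(0.02, 0.9, length.out = 10)
  expect_equal(inverse_calibration(curve, predict(curve, probes)),
               probes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_calibration_curve(c(0.1, 1), c(1, 2)), "4 distinct")
  expect_error(fit_calibration_curve(concs, rev(h)), "fit")
})

test_that("poly_log calibration enforces monotonicity over the data range", {
  concs <- c(0.01, 0.03, 0.1, 0.3, 1)
  h <- 0.5 + 0.2 * log10(concs) + 0.01 * log10(concs)^2
  curve <- fit_calibration_curve(concs, h, form = "poly_log")
  expect_equal(predict(curve, concs), h, tolerance = 1e-9)
  probes <- c(0.02, 0.05, 0.2, 0.6)
  expect_equal(inverse_calibration(curve, predict(curve, probes)),
               probes, tolerance = 1e-6, ignore_attr = TRUE)
  h_bad <- 0.5 - 0.3 * log10(concs) - 0.2 * log10(concs)^2
  expect_error(fit_calibration_curve(concs, pmax(h_bad, 0.01),
                                     form = "poly_log"), "monotone|fit")
})

test_that("LOD follows the signal-to-noise criterion", {
  concs <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)
  curve <- fit_calibration_curve(concs, 1 * concs / (0.35 + concs))
  sdb <- 0.01
  lod <- estimate_lod(curve, sdb, snr = 3.5)
  target <- 3.5 * sdb
  expect_equal(target, predict(curve, lod), tolerance = 1e-9,
               ignore_attr = TRUE)
  # closed form for the Hill inverse
  expect_equal(as.numeric(lod), curve$K * target / (curve$h_max - target),
               tolerance = 1e-9)
  expect_equal(as.numeric(estimate_lod(curve, sdb, snr = 0)), 0)
  # monotone in blank_sd and snr
  expect_gt(estimate_lod(curve, 2 * sdb), lod)
  expect_gt(estimate_lod(curve, sdb, snr = 7), lod)
  # near-linear regime: doubling the noise doubles the LOD
  lin <- fit_calibration_curve(concs, 100 * concs / (100 + concs))
  expect_equal(as.numeric(estimate_lod(lin, 2 * sdb)) /
                 as.numeric(estimate_lod(lin, sdb)), 2, tolerance = 0.01)
  expect_error(estimate_lod(curve, 10), "not detectable")
  expect_error(estimate_lod(curve, 0), "positive")
})

test_that("the conversion chain recovers the worked mixture concentrations", {
  refs <- default_reference_library()
  responses <- default_response_models()
  curves <- fit_calibration_set(responses)
  blank <- make_blank(refs$grid, noise_config(0, 0, 0.1))
  concs <- ratio_to_concentrations(1, c(5, 2, 1, 1, 1))
  heights <- mapply(response_height, responses, concs)
  S <- sum(heights)
  smp <- compose_mixture(heights / S, refs, blank, noiseless_cfg(),
                         scale = S)
  pred <- c(smp$contributions, smp$norm_factor)
  q <- contributions_to_concentrations(pred, smp$raw_max, curves)
  expect_equal(unname(q$concentrations), concs, tolerance = 0.01)
})

test_that("conversion floors negatives and is invariant to label rescaling", {
  responses <- default_response_models()
  curves <- fit_calibration_set(responses)
  pred <- c(-0.2, 0.3, 0.1, 0.05, 0.02, 1.1)
  q <- contributions_to_concentrations(pred, raw_max = 0.8, curves)
  expect_equal(unname(q$concentrations[1]), 0)
  expect_true(all(q$concentrations >= 0))
  q2 <- contributions_to_concentrations(pred * 2, raw_max = 0.8, curves)
  expect_equal(q2$concentrations, q$concentrations, tolerance = 1e-12)
  expect_error(contributions_to_concentrations(c(0.5, 0.2, 0.1, 0.1, 0.1, 0),
                                               0.8, curves), "degenerate")
  expect_error(contributions_to_concentrations(pred, 0, curves), "positive")
})
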