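test_that("confusion counts match a hand count on random pairs", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]), c(tp = 2, tn = 2,
                                                        fp = 0, fn = 0))
  cm2 <- confusion(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(cm2$tp + cm2$tn, 0)
  set.seed(16)
  for (i in 1:30) {
    p <- rbinom(25, 1, 0.5); t <- rbinom(25, 1, 0.5)
    cm <- confusion(p, t)
    expect_equal(cm$tp, sum(p & t))
    expect_equal(cm$fp, sum(p & !t))
    expect_equal(cm$tn, sum(!p & !t))
    expect_equal(cm$fn, sum(!p & t))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 25)
  }
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "lengths")
})

test_that("class metrics follow their definitions and flag undefined cases", {
  perfect <- class_metrics(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_true(all(unlist(perfect) == 1))
  m <- class_metrics(structure(list(tp = 3, fp = 1, fn = 1, tn = 5),
                               class = "confusion_matrix"))
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$npv, 5 / 6)
  undef <- class_metrics(structure(list(tp = 0, fp = 0, fn = 2, tn = 3),
                                   class = "confusion_matrix"))
  expect_true(is.na(undef$precision))
  expect_true(is.na(undef$f1))
  expect_equal(undef$specificity, 1)
})

test_that("micro pools counts while macro averages targets", {
  one <- confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  mm <- micro_macro(list(one, one, one, one, one))
  expect_equal(unlist(mm$micro), unlist(class_metrics(one)))
  expect_equal(unlist(mm$macro), unlist(class_metrics(one)))
  # disjoint supports: micro equals metrics of the pooled counts
  a <- confusion(c(1, 1, 0), c(1, 0, 0))
  b <- confusion(c(0, 0, 1), c(0, 1, 1))
  mm2 <- micro_macro(list(a, b))
  pooled <- structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                           tn = a$tn + b$tn, fn = a$fn + b$fn),
                      class = "confusion_matrix")
  expect_equal(unlist(mm2$micro), unlist(class_metrics(pooled)))
  # undefined per-target metric excluded from macro with a warning
  c_undef <- structure(list(tp = 0, fp = 0, fn = 1, tn = 2),
                       class = "confusion_matrix")
  w <- capture_warnings(mm3 <- micro_macro(list(a, c_undef)))
  expect_true(all(grepl("undefined", w)) && length(w) >= 1)
  expect_equal(mm3$macro$precision, class_metrics(a)$precision)
})

test_that("ROC endpoints, extremes and AUC obey the rank-statistic oracle", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  n <- nrow(r$points)
  expect_equal(r$points$fpr[n], 1); expect_equal(r$points$tpr[n], 1)
  expect_equal(roc_curve(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(runif(4), rep(1, 4)), "both classes")
  # AUC = Mann-Whitney U / (n+ * n-)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:200, 1)
    scores <- round(runif(n), 2)
    truth <- rbinom(n, 1, 0.4)
    if (all(truth == 1) || all(truth == 0)) next
    rk <- rank(scores)
    npos <- sum(truth == 1)
    u <- sum(rk[truth == 1]) - npos * (npos + 1) / 2
    expect_equal(roc_curve(scores, truth)$auc,
                 u / (npos * sum(truth == 0)), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(18)
  scores <- runif(80)
  truth <- rbinom(80, 1, 0.5)
  ours <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("spectral and concentration RMSE match the defining formulas", {
  expect_equal(rmse_spectrum(matrix(c(0.1, 0), 1), matrix(0, 1, 2)),
               sqrt(0.01 / 2))
  expect_equal(rmse_conc(matrix(c(0.1, 0, 0, 0, 0), 1), matrix(0, 1, 5)),
               sqrt(0.01 / 5))
  set.seed(19)
  for (i in 1:20) {
    n <- sample(2:8, 1); w <- sample(3:12, 1)
    P <- matrix(rnorm(n * w), n); A <- matrix(rnorm(n * w), n)
    # independent naive double-loop evaluation
    acc <- 0
    for (ii in 1:n) for (kk in 1:w) acc <- acc + (P[ii, kk] - A[ii, kk])^2
    naive <- sqrt(acc / (n * w))
    expect_equal(rmse_spectrum(P, A), naive, tolerance = 1e-12)
    expect_equal(rmse_conc(P, A), naive, tolerance = 1e-12)
    # homogeneity of degree 1 in the error
    expect_equal(rmse_spectrum(A + 2 * (P - A), A), 2 * rmse_spectrum(P, A),
                 tolerance = 1e-12)
    # permutation invariance over samples
    o <- sample(n)
    expect_equal(rmse_conc(P[o, , drop = FALSE], A[o, , drop = FALSE]),
                 rmse_conc(P, A), tolerance = 1e-12)
  }
  expect_equal(rmse_spectrum(diag(3), diag(3)), 0)
  expect_error(rmse_spectrum(matrix(0, 2, 3), matrix(0, 3, 2)), "shapes")
})

test_that("predicted-spectrum reconstruction inverts the simulator", {
  refs <- default_reference_library()
  blank0 <- make_blank(refs$grid, noise_config(0, 0, 0))
  set.seed(20)
  ctr <- sample_contributions(zero_prob = 0)
  smp <- compose_mixture(ctr, refs, blank0, noiseless_cfg(), scale = 2)
  rec <- reconstruct_predicted_spectrum(c(smp$contributions,
                                          smp$norm_factor),
                                        refs, smp$raw_max)
  expect_equal(rec$intensities, smp$spectrum$intensities, tolerance = 1e-6)
  zero <- reconstruct_predicted_spectrum(c(rep(0, 5), 1), refs, 1)
  expect_equal(zero$intensities, rep(0, refs$grid$n_points))
  single <- reconstruct_predicted_spectrum(c(1, 0, 0, 0, 0, 2), refs, 4)
  expect_equal(single$intensities, 0.5 * refs$spectra$PY$intensities,
               tolerance = 1e-12)
})
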