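#' Binary confusion matrix
#'
#' @param pred,truth binary vectors of equal length.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("confusion: pred and truth lengths differ")
  pred <- as.integer(pred); truth <- as.integer(truth)
  structure(list(tp = sum(pred == 1L & truth == 1L),
                 fp = sum(pred == 1L & truth == 0L),
                 tn = sum(pred == 0L & truth == 0L),
                 fn = sum(pred == 0L & truth == 1L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' Precision, sensitivity (recall), specificity, negative predictive value,
#' F1 (harmonic mean of precision and sensitivity), plus per-call accuracy.
#' Metrics with a zero denominator are reported as `NA` (flagged undefined),
#' never coerced to 0 or 1.
#'
#' @param cm a [confusion()] object.
#' @return An object of class `class_metrics`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp)
  sensitivity <- safe_ratio(cm$tp, cm$tp + cm$fn)
  specificity <- safe_ratio(cm$tn, cm$tn + cm$fp)
  npv <- safe_ratio(cm$tn, cm$tn + cm$fn)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  accuracy <- safe_ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, npv = npv, f1 = f1,
                 accuracy = accuracy), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Micro and macro averages over per-target confusion matrices
#'
#' Micro metrics come from the elementwise-summed matrix (pooled counts);
#' macro metrics are the unweighted mean of per-target metrics, excluding
#' undefined (`NA`) entries with a warning.
#'
#' @param per_target list of [confusion()] objects (one per target).
#' @return A list with `micro` and `macro` [class_metrics()] and `pooled`
#'   (the summed confusion matrix).
#' @export
micro_macro <- function(per_target) {
  if (!length(per_target)) stop("micro_macro: need at least one matrix")
  pooled <- structure(list(
    tp = sum(vapply(per_target, `[[`, numeric(1), "tp")),
    fp = sum(vapply(per_target, `[[`, numeric(1), "fp")),
    tn = sum(vapply(per_target, `[[`, numeric(1), "tn")),
    fn = sum(vapply(per_target, `[[`, numeric(1), "fn"))),
    class = "confusion_matrix")
  micro <- class_metrics(pooled)
  per <- lapply(per_target, class_metrics)
  macro_vals <- lapply(names(unclass(micro)), function(nm) {
    v <- vapply(per, `[[`, numeric(1), nm)
    if (anyNA(v))
      warning(sprintf("micro_macro: %s undefined for %d target(s); excluded from macro",
                      nm, sum(is.na(v))))
    mean(v, na.rm = TRUE)
  })
  macro <- structure(stats::setNames(macro_vals, names(unclass(micro))),
                     class = "class_metrics")
  list(micro = micro, macro = macro, pooled = pooled, per_target = per)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the threshold over the unique scores (positive call at
#' `score >= threshold`, matching [classify()]), producing operating points
#' from (0, 0) to (1, 1) and the trapezoidal area under the curve.
#'
#' @param scores numeric score vector.
#' @param truth binary vector; both classes must be present.
#' @return An object of class `roc_result`: data frame `points`
#'   (`threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (all(truth == 1L) || all(truth == 0L))
    stop("roc_curve: truth must contain both classes")
  npos <- sum(truth == 1L); nneg <- sum(truth == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call <- scores >= thr[i]
    tpr[i] <- sum(call & truth == 1L) / npos
    fpr[i] <- sum(call & truth == 0L) / nneg
  }
  o <- order(fpr, tpr)
  pts <- data.frame(threshold = thr[o], fpr = fpr[o], tpr = tpr[o])
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d operating points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Micro- and macro-averaged multilabel ROC-AUC
#'
#' Micro pools all targets' (score, truth) pairs into one curve; macro
#' averages the per-target AUCs.
#'
#' @param scores `n x 5` score matrix.
#' @param truth `n x 5` binary presence matrix.
#' @return List with `per_target` ROC results, `micro` ROC result and
#'   `macro_auc`.
#' @export
multilabel_roc <- function(scores, truth) {
  stopifnot(all(dim(scores) == dim(truth)))
  per <- lapply(seq_len(ncol(scores)), function(j)
    roc_curve(scores[, j], truth[, j]))
  names(per) <- colnames(truth)
  micro <- roc_curve(as.vector(scores), as.vector(truth))
  list(per_target = per, micro = micro,
       macro_auc = mean(vapply(per, `[[`, numeric(1), "auc")))
}

#' Spectral root-mean-squared error
#'
#' `sqrt( sum_i sum_k (pred_ik - actual_ik)^2 / (n * w) )` over n spectra of
#' w points each, computed on the max-normalized scale the models operate
#' on.
#'
#' @param pred,actual matrices (n x w) or [spectrum_set()]s on one grid.
#' @return Dimensionless scalar RMSE.
#' @export
rmse_spectrum <- function(pred, actual) {
  P <- if (inherits(pred, "spectrum_set")) set_matrix(pred) else as.matrix(pred)
  A <- if (inherits(actual, "spectrum_set")) set_matrix(actual) else as.matrix(actual)
  if (!all(dim(P) == dim(A)))
    stop("rmse_spectrum: prediction and truth shapes differ")
  sqrt(sum((P - A)^2) / length(A))
}

#' Concentration root-mean-squared error
#'
#' `sqrt( sum_i sum_j (pred_ij - actual_ij)^2 / (n * m) )` over n samples and
#' m targets, in uM.
#'
#' @param pred,actual `n x m` concentration matrices (uM).
#' @return RMSE in uM.
#' @export
rmse_conc <- function(pred, actual) {
  P <- as.matrix(pred); A <- as.matrix(actual)
  if (!all(dim(P) == dim(A)))
    stop("rmse_conc: prediction and truth shapes differ")
  sqrt(sum((P - A)^2) / length(A))
}

#' Reconstruct a predicted spectrum from regression labels
#'
#' Scaled addition of the unit-max references under the predicted labels:
#' `sum_i (l_i / z) * raw_max * R_i`, returned on the normalized comparison
#' scale (divided by `raw_max`) used by [rmse_spectrum()].
#'
#' @param pred_labels 6-vector `(l1..l5, z)`.
#' @param refs reference [spectrum_set()].
#' @param raw_max raw maximum of the test spectrum.
#' @param z_floor degenerate-normalization guard.
#' @return A [spectrum_1d()] labelled `"reconstruction"`.
#' @export
reconstruct_predicted_spectrum <- function(pred_labels, refs, raw_max,
                                           z_floor = 1e-6) {
  if (length(pred_labels) != length(refs$spectra) + 1L)
    stop("reconstruct_predicted_spectrum: need 5 contributions plus z")
  z <- pred_labels[length(pred_labels)]
  if (z <= z_floor)
    stop("reconstruct_predicted_spectrum: degenerate normalization factor")
  l <- pmax(pred_labels[-length(pred_labels)], 0)
  y <- numeric(refs$grid$n_points)
  for (i in seq_along(l))
    if (l[i] > 0) y <- y + (l[i] / z) * raw_max * refs$spectra[[i]]$intensities
  spectrum_1d(y / raw_max, refs$grid, "reconstruction")
}

#' Full classification report for one test set
#'
#' @param calls,truth `n x 5` binary matrices.
#' @param scores `n x 5` score matrix (for ROC).
#' @return A list with per-target metrics, micro/macro averages, subset
#'   accuracy (every call on a sample correct) and pooled per-call accuracy,
#'   plus ROC results when scores are supplied.
#' @export
classification_report <- function(calls, truth, scores = NULL) {
  stopifnot(all(dim(calls) == dim(truth)))
  per_cm <- lapply(seq_len(ncol(calls)), function(j)
    confusion(calls[, j], truth[, j]))
  names(per_cm) <- colnames(truth)
  mm <- suppressWarnings(micro_macro(per_cm))
  out <- list(confusions = per_cm, per_target = mm$per_target,
              micro = mm$micro, macro = mm$macro,
              subset_accuracy = mean(rowSums(calls == truth) == ncol(truth)),
              percall_accuracy = mean(calls == truth))
  if (!is.null(scores)) {
    both <- vapply(seq_len(ncol(truth)), function(j) {
      v <- truth[, j]; any(v == 1L) && any(v == 0L)
    }, logical(1))
    if (all(both)) out$roc <- multilabel_roc(scores, truth)
  }
  out
}
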