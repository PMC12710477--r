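## Area under the precision-recall curve (average precision): sum over the
## ranking of precision at each positive, i.e. sum (R_i - R_{i-1}) * P_i.
averagePrecision <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  dRec <- diff(c(0, rec))
  sum(dRec * prec)
}

#' Regression and classification metrics for synergy prediction
#'
#' MSE, Spearman rank correlation (average ranks on ties), coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, and -- after binarizing
#' the true scores at `threshold` -- AUC and AUPR of the continuous
#' predictions. When only one class remains after thresholding, AUC/AUPR are
#' reported as NA with `classesPresent = FALSE`; the regression metrics are
#' still computed.
#'
#' @param yTrue observed synergy scores (length >= 2).
#' @param yPred predicted scores, same length.
#' @param threshold binarization threshold on `yTrue` (default 0, the mean
#'   of standardized scores).
#' @return list with mse, scc, r2, auc, aupr, n, classesPresent.
#' @examples
#' computeMetrics(c(1, 2, 3, -1), c(0.9, 1.8, 2.7, -0.5))
#' @export
computeMetrics <- function(yTrue, yPred, threshold = 0) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  mse <- mean((yTrue - yPred)^2)
  scc <- stats::cor(yTrue, yPred, method = "spearman")
  r2 <- 1 - sum((yTrue - yPred)^2) / sum((yTrue - mean(yTrue))^2)
  labels <- as.integer(yTrue > threshold)
  if (length(unique(labels)) < 2L) {
    auc <- NA_real_; aupr <- NA_real_; present <- FALSE
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = yPred, direction = "<",
      levels = c(0L, 1L), quiet = TRUE)))
    aupr <- averagePrecision(labels, yPred)
    present <- TRUE
  }
  list(mse = mse, scc = scc, r2 = r2, auc = auc, aupr = aupr,
       n = length(yTrue), classesPresent = present)
}
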