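#' Classification metrics for scored pairs
#'
#' AUC by the rank statistic (ties averaged), AUPR by step integration of
#' the precision-recall curve over score thresholds, and F1, Accuracy and
#' Recall at the 0.5 decision threshold.
#'
#' @param scores numeric prediction scores in `[0,1]`.
#' @param labels binary labels, same length, both classes present.
#' @return named numeric vector `AUC, AUPR, F1, Accuracy, Recall`.
#' @examples
#' computeMetrics(c(0.9, 0.8, 0.1), c(1, 1, 0))  # AUC 1, Recall 1
#' @export
computeMetrics <- function(scores, labels) {
    if (length(scores) != length(labels) || length(scores) < 2L)
        stopTyped("preconditionError",
                  "scores and labels must align with length >= 2")
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stopTyped("undefinedMetricError",
                  "both classes must be present to compute metrics")
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    # PR curve over descending unique score thresholds
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    cumTP <- cumsum(l); cumFP <- cumsum(1L - l)
    last <- c(s[-1L] != s[-length(s)], TRUE)   # threshold block ends
    tp <- cumTP[last]; fp <- cumFP[last]
    prec <- tp / (tp + fp)
    rec <- tp / nPos
    aupr <- sum(diff(c(0, rec)) * prec)
    pred <- as.integer(scores >= 0.5)
    TP <- sum(pred == 1L & labels == 1L)
    FP <- sum(pred == 1L & labels == 0L)
    FN <- sum(pred == 0L & labels == 1L)
    f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
    c(AUC = auc, AUPR = aupr, F1 = f1,
      Accuracy = mean(pred == labels), Recall = TP / nPos)
}
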