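# classification metric battery

binary_confusion <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

f1_from_confusion <- function(cm) {
  denom <- 2 * cm["tp"] + cm["fp"] + cm["fn"]
  if (denom == 0) return(0)
  unname(2 * cm["tp"] / denom)
}

mcc_binary <- function(cm) {
  num <- cm["tp"] * cm["tn"] - cm["fp"] * cm["fn"]
  den <- sqrt(prod(c(cm["tp"] + cm["fp"], cm["tp"] + cm["fn"],
                     cm["tn"] + cm["fp"], cm["tn"] + cm["fn"])))
  if (den == 0) return(0)
  unname(num / den)
}

# generalized (Gorodkin) correlation for a k-class confusion matrix
mcc_multiclass <- function(truth, pred, classes) {
  C <- table(factor(truth, classes), factor(pred, classes))
  s <- sum(C); c_diag <- sum(diag(C))
  t_k <- rowSums(C); p_k <- colSums(C)
  num <- c_diag * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# rank-statistic AUC with midranks for ties
auc_rank <- function(truth, scores, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-wise integral of the PR curve over thresholds)
average_precision <- function(truth, scores, positive) {
  pos <- truth == positive
  n1 <- sum(pos)
  if (n1 == 0 || all(pos)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; scores <- scores[ord]
  ap <- 0; tp <- 0; n_seen <- 0; prev_recall <- 0
  for (s in unique(scores)) {
    grp <- which(scores == s)
    tp <- tp + sum(pos[grp])
    n_seen <- n_seen + length(grp)
    recall <- tp / n1
    precision <- tp / n_seen
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Classification metric battery
#'
#' Binary tasks report accuracy, F1, AUC (rank statistic with midranks),
#' AUPR (average precision) and the Matthews correlation coefficient;
#' multiclass tasks report accuracy, macro-F1 (unweighted mean of per-class
#' F1) and the generalized multiclass MCC. AUC/AUPR require `scores` and are
#' reported as `NA` when undefined (single-class truth, or multiclass).
#'
#' @param truth,pred Aligned label vectors.
#' @param scores Optional numeric score of the positive class (binary only;
#'   the positive class is the last of `classes`).
#' @param classes Ordered class labels; defaults to the sorted union.
#' @return An object of class `classification_metrics`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  acc <- mean(truth == pred)
  if (length(classes) == 2) {
    positive <- classes[2]
    cm <- binary_confusion(truth, pred, positive)
    out <- list(task = "binary", classes = classes,
                accuracy = acc, f1 = f1_from_confusion(cm),
                mcc = mcc_binary(cm),
                auc = if (is.null(scores)) NA_real_
                      else auc_rank(truth, scores, positive),
                aupr = if (is.null(scores)) NA_real_
                       else average_precision(truth, scores, positive),
                confusion = cm)
  } else {
    per_f1 <- vapply(classes, function(k)
      f1_from_confusion(binary_confusion(truth, pred, k)), 0)
    out <- list(task = "multiclass", classes = classes,
                accuracy = acc, macro_f1 = mean(per_f1),
                mcc = mcc_multiclass(truth, pred, classes),
                auc = NA_real_, aupr = NA_real_)
  }
  structure(out, class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  if (x$task == "binary")
    cat(sprintf(
      "Binary metrics: accuracy %.3f | F1 %.3f | AUC %s | AUPR %s | MCC %.3f\n",
      x$accuracy, x$f1,
      ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
      ifelse(is.na(x$aupr), "NA", sprintf("%.3f", x$aupr)), x$mcc))
  else
    cat(sprintf(
      "Multiclass metrics (%d classes): accuracy %.3f | macro-F1 %.3f | MCC %.3f\n",
      length(x$classes), x$accuracy, x$macro_f1, x$mcc))
  invisible(x)
}

#' Exponentially smoothed metric trace
#'
#' Dashboard-style smoothing `s_t = w * s_(t-1) + (1 - w) * x_t` with
#' `s_1 = x_1`.
#'
#' @param x Numeric trace.
#' @param weight Smoothing weight in `[0, 1)`.
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(x, weight = 0.25) {
  if (length(x) == 0) return(x)
  out <- numeric(length(x))
  out[1] <- x[1]
  for (t in seq_along(x)[-1]) out[t] <- weight * out[t - 1] + (1 - weight) * x[t]
  out
}
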