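# classification metrics against arithmetic and brute-force oracles

labels_from_confusion <- function(tp, fp, fn, tn) {
  truth <- c(rep("pos", tp), rep("neg", fp), rep("pos", fn), rep("neg", tn))
  pred <- c(rep("pos", tp + fp), rep("neg", fn + tn))
  list(truth = truth, pred = pred)
}

test_that("metrics match the hand-computed confusion matrix", {
  z <- labels_from_confusion(tp = 40, fp = 10, fn = 5, tn = 45)
  m <- compute_metrics(z$truth, z$pred, classes = c("neg", "pos"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 80 / 95)
  expect_equal(m$mcc, (40 * 45 - 10 * 5) / sqrt(50 * 45 * 55 * 50))
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)
})

test_that("perfect, inverted and degenerate predictions hit the extremes", {
  truth <- rep(c("neg", "pos"), each = 10)
  perfect <- compute_metrics(truth, truth, scores = c(rep(0, 10), rep(1, 10)),
                             classes = c("neg", "pos"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$mcc, 1)

  inverted <- compute_metrics(truth, rev(truth), classes = c("neg", "pos"))
  expect_equal(inverted$mcc, -1)

  single <- compute_metrics(rep("pos", 5), rep("pos", 5),
                            scores = runif(5), classes = c("neg", "pos"))
  expect_true(is.na(single$auc))
})

test_that("random scores on a balanced task give chance-level AUC", {
  set.seed(30)
  truth <- rep(c("neg", "pos"), 1000)
  scores <- runif(2000)
  m <- compute_metrics(truth, ifelse(scores > 0.5, "pos", "neg"), scores,
                       classes = c("neg", "pos"))
  expect_lt(abs(m$auc - 0.5), 0.03)
  expect_lt(abs(m$aupr - 0.5), 0.03)
})

test_that("metrics agree with brute-force oracles on random settings", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(c("neg", "pos"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("neg", "pos")
    scores <- round(runif(n), 2)  # rounding forces score ties
    pred <- ifelse(scores > runif(1), "pos", "neg")
    m <- compute_metrics(truth, pred, scores, classes = c("neg", "pos"))

    # AUC oracle: all positive/negative pair comparisons with 0.5 for ties
    pos_s <- scores[truth == "pos"]; neg_s <- scores[truth == "neg"]
    cmp <- outer(pos_s, neg_s, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(m$auc, mean(cmp), tolerance = 1e-9)

    # average-precision oracle: precision at each positive, scanning by
    # descending score with ties processed as one block
    ord <- order(-scores)
    ap <- 0; tp <- 0; seen <- 0; prev_r <- 0; npos <- sum(truth == "pos")
    for (s in unique(sort(scores, decreasing = TRUE))) {
      blk <- which(scores == s)
      tp <- tp + sum(truth[blk] == "pos"); seen <- seen + length(blk)
      ap <- ap + (tp / npos - prev_r) * (tp / seen)
      prev_r <- tp / npos
    }
    expect_equal(m$aupr, ap, tolerance = 1e-9)

    # MCC oracle from raw confusion counts
    tp_ <- sum(truth == "pos" & pred == "pos")
    fp_ <- sum(truth == "neg" & pred == "pos")
    fn_ <- sum(truth == "pos" & pred == "neg")
    tn_ <- sum(truth == "neg" & pred == "neg")
    den <- sqrt(tp_ + fp_) * sqrt(tp_ + fn_) * sqrt(tn_ + fp_) * sqrt(tn_ + fn_)
    expect_equal(m$mcc, if (den == 0) 0 else (tp_ * tn_ - fp_ * fn_) / den,
                 tolerance = 1e-9)
  }
})

test_that("binary AUC agrees with an established implementation", {
  set.seed(32)
  truth <- sample(c("neg", "pos"), 200, replace = TRUE)
  scores <- runif(200) + 0.3 * (truth == "pos")
  m <- compute_metrics(truth, ifelse(scores > 0.5, "pos", "neg"), scores,
                       classes = c("neg", "pos"))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(m$auc, ref, tolerance = 1e-9)
})

test_that("multiclass metrics use macro-F1 and the generalized MCC", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  m <- compute_metrics(truth, pred, classes = c("a", "b", "c"))
  expect_equal(m$task, "multiclass")
  expect_equal(m$accuracy, 4 / 6)
  # per-class F1 by hand: a: P=1/2,R=1/2 -> 1/2; b: P=2/3,R=1 -> 4/5; c: P=1,R=1/2 -> 2/3
  expect_equal(m$macro_f1, mean(c(1 / 2, 4 / 5, 2 / 3)))
  # Gorodkin form from the confusion matrix
  C <- table(factor(truth, c("a", "b", "c")), factor(pred, c("a", "b", "c")))
  s <- sum(C); tr <- sum(diag(C))
  num <- tr * s - sum(rowSums(C) * colSums(C))
  den <- sqrt(s^2 - sum(colSums(C)^2)) * sqrt(s^2 - sum(rowSums(C)^2))
  expect_equal(m$mcc, num / den)
  expect_true(is.na(m$auc))

  perfect <- compute_metrics(truth, truth, classes = c("a", "b", "c"))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$macro_f1, 1)
})

test_that("trace smoothing follows the stated recurrence", {
  x <- c(1, 0, 1, 1)
  s <- smooth_trace(x, weight = 0.25)
  expect_equal(s[1], 1)
  expect_equal(s[2], 0.25 * 1 + 0.75 * 0)
  expect_equal(s[3], 0.25 * s[2] + 0.75 * 1)
  expect_length(smooth_trace(numeric(0)), 0)
})
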