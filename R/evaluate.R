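#' Train/test split
#'
#' Disjoint, exhaustive partition of the activity table's molecules,
#' stratified by class by default: a plain random 20% split of a set with
#' only a few dozen positives can leave the test set without positives,
#' making AUC undefined, so stratification preserves the class ratio in
#' both parts.  Non-stratified mode is retained for strict replication of a
#' plain random partition.
#'
#' @param labels activity table (data.frame with id, label).
#' @param test_fraction fraction held out (default 0.2).
#' @param seed RNG seed; same seed, same split.
#' @param stratified stratify by label (default TRUE).
#' @return list with character vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0,1), got ", test_fraction)
  set.seed(seed)
  ids <- labels$id
  if (stratified) {
    test <- character(0)
    for (cl in unique(labels$label)) {
      cl_ids <- ids[labels$label == cl]
      if (length(cl_ids) < 2 / test_fraction)
        stop("class ", cl, " has only ", length(cl_ids),
             " members; too small to stratify at fraction ", test_fraction,
             " - consider stratified = FALSE")
      n_test <- round(length(cl_ids) * test_fraction)
      test <- c(test, sample(cl_ids, n_test))
    }
  } else {
    test <- sample(ids, round(length(ids) * test_fraction))
  }
  list(train = setdiff(ids, test), test = test)
}

#' Confusion counts
#'
#' @param pred predicted labels (0/1).
#' @param truth true labels (0/1).
#' @return list with tp, tn, fp, fn.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("length mismatch: ", length(pred), " vs ", length(truth))
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  list(tp = sum(pred == 1L & truth == 1L),
       tn = sum(pred == 0L & truth == 0L),
       fp = sum(pred == 1L & truth == 0L),
       fn = sum(pred == 0L & truth == 1L))
}

#' ROC curve and area under it
#'
#' Sweeps the positive-accepting threshold over the unique score values
#' (tied scores cross the threshold together), accumulating sensitivity
#' TP/(TP+FN) against the false positive rate 1 - specificity, and
#' integrates by the trapezoidal rule — which makes the AUC identical to
#' the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counted half.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth binary labels (0/1); both classes must be present.
#' @return list with thresholds (descending), tpr, fpr, auc.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: need both classes, got ", np, " pos / ", nn, " neg")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & truth == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & truth == 0L), numeric(1))
  tpr <- c(0, tp / np, 1)
  fpr <- c(0, fp / nn, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' Returns 0 when any denominator factor is zero (the field-standard
#' convention, keeping the statistic defined on degenerate tables).
#'
#' @param c confusion counts from [confusion()].
#' @return value in \[-1, 1\].
#' @export
mcc <- function(c) {
  with(c, {
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
  })
}

#' Build an evaluation report
#'
#' Bundles the confusion table at the given threshold, ROC/AUC and MCC for
#' a set of scored instances.
#'
#' @param scores posterior scores.
#' @param truth binary labels.
#' @param threshold classification cutoff (default 0.5).
#' @return list with auc, mcc, confusion, roc, n, threshold.
#' @export
evaluation_report <- function(scores, truth, threshold = 0.5) {
  roc <- roc_auc(scores, truth)
  conf <- confusion(as.integer(scores > threshold), truth)
  list(auc = roc$auc, mcc = mcc(conf), confusion = conf,
       roc = list(thresholds = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
       n = length(truth), threshold = threshold)
}
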