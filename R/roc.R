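# ROC/AUC evaluation. Scores are used as-is (higher score predicts the
# positive class); an AUC below 0.5 is reported, never auto-flipped, because
# marker directionality is biologically meaningful.

# Normalize labels to logical TRUE = positive.
as_positive <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.character(labels)
    assert_that(!is.null(positive), "positive class must be named for non-logical labels")
    pos <- labels == positive
  }
  assert_that(any(pos) && any(!pos), "need both classes present")
  pos
}

#' ROC curve
#'
#' Empirical ROC staircase for a score vector and binary labels. Thresholds
#' are taken at midpoints between distinct sorted scores (plus sentinels
#' above the maximum and below the minimum); a sample is predicted positive
#' when its score is at or above the threshold. The curve runs monotonically
#' from (0,0) to (1,1).
#'
#' @param scores numeric scores (e.g. log2 expression), higher predicting the
#'   positive class.
#' @param labels logical (TRUE = positive) or character/factor plus
#'   `positive`.
#' @param positive positive class label when `labels` is not logical.
#' @return data.frame: `threshold`, `fpr`, `tpr`, `sensitivity`,
#'   `specificity`, one row per threshold, ordered from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  pos <- as_positive(labels, positive)
  assert_that(length(scores) == length(pos), "scores and labels differ in length")
  assert_that(!anyNA(scores), "scores contain NA")
  s <- sort(unique(scores))
  thr <- c(Inf, rev(if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric()), -Inf)
  # rev(): thresholds descend from +Inf, so fpr/tpr ascend from (0,0)
  n1 <- sum(pos); n0 <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr,
             sensitivity = tpr, specificity = 1 - fpr)
}

#' Area under the ROC curve
#'
#' Midrank (Mann-Whitney) AUC: the probability that a random positive sample
#' scores above a random negative one, ties counted one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive = NULL) {
  pos <- as_positive(labels, positive)
  assert_that(!anyNA(scores), "scores contain NA")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval over bootstrap resamples drawn within each class
#' (stratified, so every resample contains both classes). Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @inheritParams roc_curve
#' @param n_boot number of resamples, default 2000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed, or `NULL` to draw from the current stream.
#' @return list with `low`, `high`, `level`, `n_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = NULL, positive = NULL) {
  pos <- as_positive(labels, positive)
  assert_that(sum(pos) >= 2L && sum(!pos) >= 2L,
              "bootstrap CI needs >= 2 samples per class")
  i_pos <- which(pos); i_neg <- which(!pos)
  stat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ip <- sample(i_pos, replace = TRUE)
      ineg <- sample(i_neg, replace = TRUE)
      auc(c(scores[ip], scores[ineg]),
          c(rep(TRUE, length(ip)), rep(FALSE, length(ineg))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  list(low = q[1], high = q[2], level = level, n_boot = n_boot)
}

#' Youden-optimal operating point
#'
#' Picks the threshold maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken towards higher specificity, then towards the first point
#' encountered.
#'
#' @param roc a curve from [roc_curve()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_point <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)  # tolerance guards float ties in J
  if (length(best) > 1L) best <- best[order(-roc$specificity[best])][1L]
  list(threshold = roc$threshold[best], sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best], youden = j[best])
}

#' Evaluate one candidate marker by ROC analysis
#'
#' Computes AUC, a stratified bootstrap confidence interval, and the Youden
#' operating point for a gene's expression between two conditions of a
#' dataset, with the test condition as the positive class.
#'
#' @param dataset an `expression_dataset`.
#' @param gene_id gene to evaluate.
#' @param condition_pos,condition_neg condition labels (positive/negative
#'   class).
#' @param n_boot,level,seed passed to [bootstrap_auc_ci()].
#' @return one-row data.frame: `gene_id`, `comparison`, `auc`, `ci_low`,
#'   `ci_high`, `threshold`, `sensitivity`, `specificity`.
#' @export
evaluate_marker <- function(dataset, gene_id, condition_pos, condition_neg,
                            n_boot = 2000L, level = 0.95, seed = NULL) {
  validate_dataset(dataset)
  assert_that(gene_id %in% rownames(dataset$exprs), "gene '%s' not in dataset", gene_id)
  sp <- condition_samples(dataset, condition_pos)
  sn <- condition_samples(dataset, condition_neg)
  scores <- dataset$exprs[gene_id, c(sp, sn)]
  labels <- c(rep(TRUE, length(sp)), rep(FALSE, length(sn)))
  curve <- roc_curve(scores, labels)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, level = level, seed = seed)
  yp <- youden_point(curve)
  data.frame(gene_id = gene_id,
             comparison = paste0(condition_pos, "_vs_", condition_neg),
             auc = auc(scores, labels),
             ci_low = ci$low, ci_high = ci$high,
             threshold = yp$threshold, sensitivity = yp$sensitivity,
             specificity = yp$specificity,
             stringsAsFactors = FALSE)
}
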