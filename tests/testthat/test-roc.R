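test_that("roc_curve is a monotone staircase with the expected landmarks", {
  # perfect separation passes through (0, 1)
  curve <- roc_curve(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1); expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))

  # all-tied scores collapse to the diagonal
  flat <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(nrow(flat), 2)
  expect_equal(auc(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)

  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("auc is the midrank Mann-Whitney statistic, checked against brute force", {
  expect_equal(auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  set.seed(33)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)  # force ties
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels), tolerance = 1e-12)
    # complement property under sign reversal
    expect_equal(auc(-scores, labels), 1 - auc(scores, labels), tolerance = 1e-12)
    # trapezoid area under the returned curve equals the midrank AUC
    curve <- roc_curve(scores, labels)
    trap <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
    expect_equal(trap, auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("auc matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(90)
  for (i in 1:10) {
    scores <- c(rnorm(15, 1), rnorm(12))
    labels <- c(rep(1, 15), rep(0, 12))
    ref <- suppressMessages(pROC::auc(labels, scores, direction = "<"))
    expect_equal(auc(scores, labels == 1), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("stratified bootstrap CI is deterministic, degenerate on perfect separation, and calibrated", {
  scores <- c(10, 11, 12, 1, 2, 3)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 5)
  expect_equal(ci$low, 1); expect_equal(ci$high, 1)
  ci2 <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 5)
  expect_identical(ci, ci2)

  # the caller's RNG stream is not consumed
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(bootstrap_auc_ci(scores, labels, n_boot = 50, seed = 9))
  expect_identical(rnorm(1), before)

  # coverage of a null marker at n = 30 + 30: nominal 95%, allowing the
  # percentile bootstrap's known slight undercoverage plus binomial noise
  set.seed(2718)
  covered <- vapply(1:200, function(b) {
    s <- rnorm(60)
    l <- rep(c(TRUE, FALSE), each = 30)
    ci <- bootstrap_auc_ci(s, l, n_boot = 500, seed = b)
    ci$low <= 0.5 && 0.5 <= ci$high
  }, logical(1))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.995)
})

test_that("youden_point maximizes J with the higher-specificity tie-break", {
  # perfect separation
  curve <- roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  yp <- youden_point(curve)
  expect_equal(yp$sensitivity, 1); expect_equal(yp$specificity, 1)

  # diagonal curve: J = 0 everywhere, tie broken towards specificity 1
  flat <- roc_curve(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(youden_point(flat)$specificity, 1)

  # brute-force threshold scan on random instances
  set.seed(321)
  for (i in 1:20) {
    scores <- round(c(rnorm(6, 1), rnorm(6)), 1)
    labels <- rep(c(TRUE, FALSE), each = 6)
    yp <- youden_point(roc_curve(scores, labels))
    grid <- sort(unique(c(scores - 0.05, scores + 0.05)))
    j_best <- max(vapply(grid, function(t)
      mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1, numeric(1)))
    expect_equal(yp$youden, j_best, tolerance = 1e-12)
  }

  # the documented worked case: positives {2,3,4}, negatives {0,1,2.5}
  scores <- c(2, 3, 4, 0, 1, 2.5)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  yp <- youden_point(roc_curve(scores, labels))
  expect_equal(yp$sensitivity, 2 / 3)
  expect_equal(yp$specificity, 1)
})

test_that("evaluate_marker summarizes a gene's diagnostic performance", {
  s <- simulate_dataset(sim_config(seed = 62))
  g <- s$truth$marker_genes$gene_id[1]
  row <- evaluate_marker(s$dataset, g, "ATRT", "brain", n_boot = 300, seed = 4)
  expect_equal(row$comparison, "ATRT_vs_brain")
  expect_gte(row$auc, 0.9)  # separation 4 => theoretical AUC 0.998
  expect_lte(row$ci_low, row$auc)
  expect_gte(row$ci_high, row$auc)
  expect_gte(row$sensitivity, 0.8)
  expect_gte(row$specificity, 0.8)
})
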