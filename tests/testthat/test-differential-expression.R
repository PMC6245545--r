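test_that("log2 fold change is the difference of log2 group means", {
  expect_equal(log2_fold_change(rep(5, 4), rep(4, 3)), 1.0)
  expect_equal(log2_fold_change(c(1, 2, 3), c(3, 1, 2)), 0.0)
  expect_equal(log2_fold_change(c(3, 5), c(1, 3)), 2.0)
  expect_error(log2_fold_change(numeric(), 1:3), "empty")
})

test_that("welch_t reproduces the reference implementation and handles degeneracy", {
  set.seed(101)
  for (i in 1:50) {
    a <- rnorm(5, sd = runif(1, 0.5, 3))
    b <- rnorm(5, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ref <- t.test(a, b)
    mine <- welch_t(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # identical groups, and permutation invariance of the means
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(welch_t(c(1, 2, 3), c(3, 1, 2))$statistic, 0)
  # degenerate conventions
  flat <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  apart <- welch_t(c(2, 2, 2), c(3, 3))
  expect_equal(apart$p_value, 0)
  expect_true(apart$degenerate)
})

test_that("moderated t reduces to the pooled t at d0 = 0 and to a common variance at d0 = Inf", {
  set.seed(55)
  x <- matrix(rnorm(40 * 12, sd = sqrt(rchisq(40, 5) / 5)), 40,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  grp <- rep(c(FALSE, TRUE), each = 6)

  plain <- moderated_t(x, grp, d0_override = 0)
  for (i in c(1, 17, 40)) {
    ref <- t.test(x[i, grp], x[i, !grp], var.equal = TRUE)
    expect_equal(plain$statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(plain$p_value[i], ref$p.value, tolerance = 1e-10)
  }

  common <- moderated_t(x, grp, d0_override = Inf)
  s02 <- attr(common, "s02")
  se <- sqrt(s02 * (1 / 6 + 1 / 6))
  m1 <- rowMeans(x[, grp]); m0 <- rowMeans(x[, !grp])
  expect_equal(common$statistic, unname((m1 - m0) / se), tolerance = 1e-12)
  expect_true(all(is.infinite(common$df)))
})

test_that("moderated t agrees with the limma empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(99)
  G <- 400; n1 <- 4; n2 <- 6
  x <- matrix(rnorm(G * (n1 + n2), sd = sqrt(rchisq(G, 4) / 4)), G,
              dimnames = list(sprintf("g%03d", 1:G), NULL))
  grp <- factor(rep(c("ref", "test"), c(n1, n2)), levels = c("ref", "test"))
  mine <- moderated_t(x, grp)

  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t keeps its size under the null", {
  set.seed(2024)
  G <- 2000
  x <- matrix(rnorm(G * 10), G, dimnames = list(sprintf("g%04d", 1:G), NULL))
  grp <- rep(c(FALSE, TRUE), each = 5)
  res <- moderated_t(x, grp)
  # type-I error at alpha = 0.05 within binomial tolerance
  rate <- mean(res$p_value <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  # p-value uniformity under the null (moderated p on d0+dg df)
  ks <- stats::ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("run_de calls planted effects and respects thresholds", {
  s <- simulate_dataset(sim_config(seed = 17))
  ds <- s$dataset
  de <- run_de(ds, "ATRT", "brain", de_config(p_threshold = 1e-5, fc_threshold = 2))
  truth <- s$truth$de_genes
  planted <- truth[truth$comparison == "ATRT_vs_brain", ]
  got <- de[match(planted$gene_id, de$gene_id), ]
  correct <- (planted$effect > 0 & got$call == "up") |
    (planted$effect < 0 & got$call == "down")
  expect_gte(mean(correct), 0.95)
  # marker genes (effect 2.8 log2 units here) are all recovered
  mk <- s$truth$marker_genes$gene_id
  expect_true(all(de$call[match(mk, de$gene_id)] == "up"))
  # null genes essentially never pass p = 1e-5
  nulls <- setdiff(de$gene_id, planted$gene_id)
  expect_lte(mean(de$call[match(nulls, de$gene_id)] != "ns"), 1 / 300)

  # degenerate thresholds make every gene significant
  de_all <- run_de(ds, "ATRT", "brain", de_config(p_threshold = 1, fc_threshold = 1))
  expect_true(all(de_all$call != "ns"))
})

test_that("run_de is antisymmetric in its comparison and monotone in thresholds", {
  ds <- simulate_dataset(sim_config(seed = 29))$dataset
  fwd <- run_de(ds, "KRT", "kidney", de_config(p_threshold = 1e-3))
  rev <- run_de(ds, "kidney", "KRT", de_config(p_threshold = 1e-3))
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p_value, rev$p_value)
  expect_identical(fwd$gene_id[fwd$call == "up"], rev$gene_id[rev$call == "down"])
  expect_identical(fwd$gene_id[fwd$call == "down"], rev$gene_id[rev$call == "up"])

  loose <- de_genes(run_de(ds, "KRT", "kidney",
                           de_config(p_threshold = 1e-3, fc_threshold = 1.5)))
  tight_p <- de_genes(run_de(ds, "KRT", "kidney",
                             de_config(p_threshold = 1e-6, fc_threshold = 1.5)))
  tight_fc <- de_genes(run_de(ds, "KRT", "kidney",
                              de_config(p_threshold = 1e-3, fc_threshold = 2.5)))
  expect_true(all(tight_p %in% loose))
  expect_true(all(tight_fc %in% loose))
})

test_that("the DE summary is the biotype-split recount of the calls", {
  ds <- simulate_dataset(sim_config(seed = 31))$dataset
  de <- run_de(ds, "ATRT", "brain")
  s <- attr(de, "summary")
  for (i in seq_len(nrow(s))) {
    expect_equal(s$n[i], sum(de$biotype == s$biotype[i] & de$call == s$call[i]))
  }
})
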