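test_that("pearson_r matches hand-computed values and its invariances", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.9827, tolerance = 1e-4)
  expect_error(pearson_r(1:4, 1:5), "unequal")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "variance")

  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    a <- runif(1, -3, 3); b <- runif(1, -5, 5)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    if (a != 0)
      expect_equal(pearson_r(a * x + b, y), sign(a) * pearson_r(x, y),
                   tolerance = 1e-12)
  }
})

test_that("pcc_pvalue is the two-sided t-transform test", {
  expect_equal(pcc_pvalue(0, 10), 1)
  expect_equal(pcc_pvalue(1, 10), 0)
  expect_equal(pcc_pvalue(-1, 10), 0)
  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ref <- cor.test(x, y)
    expect_equal(pcc_pvalue(cor(x, y), n), ref$p.value, tolerance = 1e-12)
  }
  # monotone: for fixed n, larger |r| never gives a larger p
  r <- seq(0, 0.99, by = 0.01)
  p <- pcc_pvalue(r, 20)
  expect_true(all(diff(p) <= 0))
})

test_that("t-transform p tracks the exact permutation distribution where decisions are made", {
  # at n = 7 the exact null of r is discrete (5040 permutations); the
  # t-approximation is close where it matters (within 0.02 for
  # p_perm <= 0.01) but drifts by up to ~0.1 far from significance and can
  # disagree with individual permutation p-values by a multiplicative factor
  # right around a cutoff — the documented small-sample behavior
  set.seed(77)
  p_t <- c(); p_perm <- c()
  for (i in 1:60) {
    x <- rnorm(7)
    y <- runif(1, 0, 1.6) * x + rnorm(7)
    p_t <- c(p_t, pcc_pvalue(cor(x, y), 7))
    p_perm <- c(p_perm, oracle_perm_pvalue(x, y))
  }
  deep <- p_perm <= 0.01
  expect_gt(sum(deep), 5)
  expect_lt(max(abs(p_t[deep] - p_perm[deep])), 0.02)
  expect_lt(max(abs(p_t - p_perm)[p_perm <= 0.1]), 0.15)
  # calls at the 0.001 cutoff agree outside the discreteness band
  clear_cut <- pmax(p_t, p_perm) < 1e-4 | pmin(p_t, p_perm) > 0.02
  expect_identical((p_t < 0.001)[clear_cut], (p_perm < 0.001)[clear_cut])
  expect_gt(cor(p_t, p_perm, method = "spearman"), 0.95)
})

test_that("build_pair_network enumerates the lncRNA x PCG cross product with a state partition", {
  ds <- tiny_dataset()
  net <- build_pair_network(ds, "A")
  expect_equal(nrow(net), 2 * 4)  # 2 lncRNAs x 4 PCGs (housekeeping included)
  expect_true(all(net$state %in% c("absent", "positive", "negative")))
  expect_true(all(net$lncrna_id %in% c("LNC1", "LNC2")))
  expect_false(any(net$pcg_id %in% c("LNC1", "LNC2")))
  expect_equal(nrow(unique(net[, c("lncrna_id", "pcg_id")])), nrow(net))

  # explicit universes restrict the cross product
  net2 <- build_pair_network(ds, "A", lnc_ids = c("LNC1", "LNC2"),
                             pcg_ids = c("PCG1", "PCG2", "PCG3"))
  expect_equal(nrow(net2), 6)

  # state rule matches the cutoffs row by row
  cfg <- coexpr_config()
  manual <- ifelse(net$p_value < cfg$p_cutoff & net$pcc >= cfg$pcc_cutoff, "positive",
                   ifelse(net$p_value < cfg$p_cutoff & net$pcc <= -cfg$pcc_cutoff,
                          "negative", "absent"))
  expect_identical(net$state, manual)
})

test_that("small conditions and degenerate genes are handled explicitly", {
  ds <- tiny_dataset(n_a = 3, n_b = 6)
  expect_error(build_pair_network(ds, "A"), ">= 4")
  # zero-variance gene: absent state with a degenerate flag
  ds2 <- tiny_dataset()
  ds2$exprs["PCG1", ] <- 5
  net <- build_pair_network(ds2, "A")
  flat <- net[net$pcg_id == "PCG1", ]
  expect_true(all(flat$degenerate))
  expect_true(all(flat$state == "absent"))
})

test_that("planted pairs are detected and null pairs respect the size", {
  # 400 planted pairs at PCC 0.9, n = 31: per-pair detection probability
  # ~0.999 (Fisher-z power at the effective |r| >= 0.7 threshold)
  cfg <- sim_config(
    group_sizes = c(A = 31, B = 8),
    comparisons = list(list(test = "A", ref = "B")),
    pair_blocks = data.frame(type = "II", count = 400L, target_pcc = 0.9),
    n_pcg = 450, n_lncrna = 420, n_markers = 0, n_cancer_decoys = 0,
    n_de_per_comparison = 0, n_de_lncrna_per_comparison = 0,
    seed = 41
  )
  s <- simulate_dataset(cfg)
  net <- build_pair_network(s$dataset, "A")
  key <- paste(net$lncrna_id, net$pcg_id)
  pp <- s$truth$planted_pairs
  planted_key <- paste(pp$lncrna_id, pp$pcg_id)
  planted <- key %in% planted_key
  expect_gte(mean(net$state[planted] == "positive"), 0.99)
  # independent pairs: positive-or-negative rate bounded by the p cutoff
  # plus Monte-Carlo error (~186k null pairs)
  null_rate <- mean(net$state[!planted] != "absent")
  expect_lte(null_rate, 0.001 + 3 * sqrt(0.001 / sum(!planted)))
})
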