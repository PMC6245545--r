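test_that("the 3x3 state grid classifies exhaustively under both orientations", {
  states <- c("absent", "positive", "negative")
  grid <- expand.grid(ref = states, test = states, stringsAsFactors = FALSE)
  tab <- classify_pair(grid$ref, grid$test, orientation = "table")
  cap <- classify_pair(grid$ref, grid$test, orientation = "caption")

  # 9 cells: 1 none, 2 concordant, 6 dysregulated covering all four types
  expect_equal(sum(tab == "none"), 1)
  expect_equal(sum(tab == "concordant"), 2)
  expect_equal(sum(tab %in% c("I", "II", "III", "IV")), 6)
  expect_setequal(unique(tab[tab %in% c("I", "II", "III", "IV")]),
                  c("I", "II", "III", "IV"))

  # table orientation: type I = present in the reference, absent in the test
  expect_equal(classify_pair("positive", "absent"), "I")
  expect_equal(classify_pair("positive", "negative"), "III")
  # caption orientation: "present in the tumor, absent in the control" is I
  expect_equal(classify_pair("absent", "positive", orientation = "caption"), "I")
  # duality: the two conventions swap I<->II and III<->IV cell by cell
  swap <- c(none = "none", concordant = "concordant",
            I = "II", II = "I", III = "IV", IV = "III")
  expect_identical(unname(swap[tab]), cap)

  expect_error(classify_pair("positive", "sideways"), "states")
})

test_that("type_pairs joins two conditions, keeps only dysregulated pairs, and swaps on reversal", {
  lnc <- rep(c("L1", "L2", "L3"), each = 3)
  pcg <- rep(c("P1", "P2", "P3"), times = 3)
  st_ref <- c("positive", "absent", "negative",
              "positive", "positive", "absent",
              "absent", "negative", "absent")
  st_test <- c("absent", "positive", "positive",
               "positive", "negative", "absent",
               "absent", "negative", "negative")
  ref <- pair_table_from_states(lnc, pcg, st_ref, "ctrl")
  test_ <- pair_table_from_states(lnc, pcg, st_test, "tumor")

  typed <- type_pairs(ref, test_)
  expect_s3_class(typed, "typed_pairs")
  # manual classification: dysregulated pairs only
  expect_equal(nrow(typed), 5)
  expect_setequal(typed$dys_type, c("I", "II", "IV", "III", "II"))

  rev <- type_pairs(test_, ref)
  count <- function(x) table(factor(x$dys_type, levels = c("I", "II", "III", "IV")))
  cf <- count(typed); cr <- count(rev)
  expect_equal(unname(cf[c("I", "II", "III", "IV")]),
               unname(cr[c("II", "I", "IV", "III")]))

  # all-absent inputs give an empty table
  none <- pair_table_from_states("L1", "P1", "absent", "x")
  expect_equal(nrow(type_pairs(none, none)), 0)

  # mismatched universes are rejected with the difference listed
  expect_error(type_pairs(ref[-1, ], test_), "universes differ")
})

test_that("planted dysregulation types are recovered at n = 40 per group", {
  cfg <- sim_config(
    group_sizes = c(ATRT = 40, KRT = 40, brain = 40, kidney = 40),
    pair_blocks = data.frame(type = c("I", "II", "III", "IV"),
                             count = c(10L, 5L, 2L, 2L), target_pcc = 0.9),
    n_markers = 0, n_cancer_decoys = 0,
    seed = 404
  )
  s <- simulate_dataset(cfg)
  net_ref <- build_pair_network(s$dataset, "brain")
  net_test <- build_pair_network(s$dataset, "ATRT")
  typed <- type_pairs(net_ref, net_test, orientation = "table")

  pp <- s$truth$planted_pairs
  pp <- pp[pp$comparison == "ATRT_vs_brain", ]
  key <- paste(typed$lncrna_id, typed$pcg_id)
  got <- typed$dys_type[match(paste(pp$lncrna_id, pp$pcg_id), key)]
  recovered <- !is.na(got) & got == pp$true_type
  expect_gte(mean(recovered), 0.90)
})

test_that("count_by_tier respects nesting and partitions the pairs", {
  typed <- structure(
    data.frame(lncrna_id = paste0("L", 1:8),
               pcg_id = c("P1", "P1", "P2", "P3", "P4", "P5", "P5", "P6"),
               ref_condition = "r", test_condition = "t",
               state_ref = NA, state_test = NA,
               dys_type = c("I", "I", "II", "III", "IV", "I", "II", "I"),
               stringsAsFactors = FALSE),
    class = c("typed_pairs", "data.frame"))
  diffs <- c("P1", "P2", "P5")
  cancers <- c("P2", "P5", "PX")  # not a subset of DiffPCG universe

  counts <- count_by_tier(typed, diffs, cancers)
  expect_equal(sum(counts$n_pairs[counts$tier == "AllPCG"]), nrow(typed))
  # DiffPCG never exceeds AllPCG, CancerG never exceeds DiffPCG, per type
  wide <- reshape(counts, idvar = "dys_type", timevar = "tier", direction = "wide")
  expect_true(all(wide$n_pairs.DiffPCG <= wide$n_pairs.AllPCG))
  expect_true(all(wide$n_pairs.CancerG <= wide$n_pairs.DiffPCG))
  # CancerG = cancer list intersected with DiffPCG (P2, P5): 3 pairs
  expect_equal(sum(counts$n_pairs[counts$tier == "CancerG"]), 3)
  # AllPCG tier equals the unfiltered type counts
  expect_equal(counts$n_pairs[counts$tier == "AllPCG"],
               as.integer(table(factor(typed$dys_type,
                                       levels = c("I", "II", "III", "IV")))))
  # a disjoint cancer list zeroes the tier
  counts0 <- count_by_tier(typed, diffs, c("QQ1", "QQ2"))
  expect_true(all(counts0$n_pairs[counts0$tier == "CancerG"] == 0))
})

test_that("degree counts distinct lncRNA partners", {
  typed <- structure(
    data.frame(lncrna_id = c("L1", "L2", "L3", "L1", "L1"),
               pcg_id = c("P1", "P1", "P1", "P2", "P2"),
               ref_condition = "r", test_condition = "t",
               state_ref = NA, state_test = NA,
               dys_type = c("I", "II", "I", "I", "III"),
               stringsAsFactors = FALSE),
    class = c("typed_pairs", "data.frame"))
  deg <- compute_degree(typed)
  expect_equal(deg$degree[deg$pcg_id == "P1"], 3L)
  # the same lncRNA appearing under two types is one partner
  expect_equal(deg$degree[deg$pcg_id == "P2"], 1L)
  # absent PCGs report degree 0 when a universe is given
  deg_u <- compute_degree(typed, pcg_universe = c("P1", "P2", "P3"))
  expect_equal(deg_u$degree[deg_u$pcg_id == "P3"], 0L)
  expect_equal(nrow(compute_degree(typed[0, ])), 0)
})

test_that("pairs_from_type_counts inverts count_by_tier on nested counts", {
  counts <- expand.grid(comparison = c("c1", "c2"),
                        tier = c("AllPCG", "DiffPCG", "CancerG"),
                        dys_type = c("I", "II", "III", "IV"),
                        stringsAsFactors = FALSE)
  set.seed(6)
  base <- sample(5:40, nrow(counts) / 3, replace = TRUE)
  counts$n_pairs <- NA_integer_
  counts$n_pairs[counts$tier == "AllPCG"] <- base
  counts$n_pairs[counts$tier == "DiffPCG"] <- pmax(base - sample(0:5, length(base), TRUE), 0)
  counts$n_pairs[counts$tier == "CancerG"] <-
    pmax(counts$n_pairs[counts$tier == "DiffPCG"] - sample(0:3, length(base), TRUE), 0)

  fixtures <- pairs_from_type_counts(counts)
  for (cmp in names(fixtures)) {
    fx <- fixtures[[cmp]]
    back <- count_by_tier(fx$typed, fx$diffpcg_set, fx$cancerg_set)
    orig <- counts[counts$comparison == cmp, c("tier", "dys_type", "n_pairs")]
    merged <- merge(back, orig, by = c("tier", "dys_type"))
    expect_equal(merged$n_pairs.x, merged$n_pairs.y)
  }
})
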