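#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. Defaults
#' emulate the statistical structure of the rhabdoid-tumor cohort the pipeline
#' targets: four conditions sized 47/31/8/23 (AT/RT, KRT, normal brain, normal
#' kidney), additive Gaussian noise on the log2 scale, planted fold changes of
#' 2 log2 units, planted co-expression blocks of each dysregulation type at a
#' population PCC of 0.9, and two hub marker genes wired so that they are
#' unambiguously differentially expressed in all three standard comparisons
#' (fold-change effects well clear of the FC = 2 cutoff) and keep clearly more
#' than five lncRNA partners per comparison, the way the strong published
#' markers do (degrees 6-26, AUCs near 1).
#'
#' @param n_pcg,n_lncrna,n_housekeeping gene counts per biotype class
#'   (housekeeping genes are protein-coding, flagged `is_housekeeping`).
#' @param group_sizes named integer vector: condition -> sample count (each
#'   >= 3).
#' @param comparisons list of `list(test=, ref=)` condition pairs; the default
#'   is the standard triple (tumor vs its normal tissue twice, then the two
#'   tumor types against each other).
#' @param baseline_mean,baseline_sd mean and within-condition standard
#'   deviation of log2 expression noise.
#' @param gene_mean_sd spread of gene-level baseline means around
#'   `baseline_mean`.
#' @param de_effect absolute log2 fold change planted for DE genes.
#' @param n_de_per_comparison,n_de_lncrna_per_comparison planted DE gene counts
#'   (PCGs / lncRNAs) per comparison, disjoint across comparisons.
#' @param pair_blocks data.frame with columns `type` (`I`, `II`, `III`, `IV`
#'   or `concordant`), `count`, `target_pcc`; each planted pair uses its own
#'   lncRNA and PCG and a shared latent factor with loading
#'   `lambda = sqrt(target_pcc)` so the population correlation equals
#'   `target_pcc`. Types refer to `pair_comparison` under the reference-first
#'   ("table") orientation: type I pairs are co-expressed only in the
#'   reference condition, type II only in the test condition, III/IV in both
#'   with opposite signs.
#' @param pair_comparison index into `comparisons` the pair blocks refer to.
#' @param n_markers number of planted diagnostic marker genes (cancer-flagged
#'   PCG hubs).
#' @param marker_separation standardized mean difference Delta/sigma between
#'   the test condition of the first comparison and the normal conditions; the
#'   test condition of the second comparison receives half the shift, so
#'   markers separate all three default comparisons.
#' @param marker_degree lncRNA partners per marker; partners are split between
#'   sign-flip pairs (correlated in both tumor conditions with opposite signs)
#'   and pairs private to one tumor condition, so each marker keeps degree
#'   above five in every default comparison.
#' @param marker_pair_pcc population PCC of marker-partner pairs.
#' @param n_cancer_decoys cancer-flagged PCGs with no planted signal (funnel
#'   specificity controls).
#' @param dataset_offsets named numeric vector: dataset_id -> additive log2
#'   shift applied to every gene of the samples assigned (round-robin within
#'   condition) to that dataset; exercised by the AGC scaling stage.
#' @param seed integer seed; the whole simulation runs in one RNG stream.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_pcg = 300,
                       n_lncrna = 90,
                       n_housekeeping = 20,
                       group_sizes = c(ATRT = 47, KRT = 31, brain = 8, kidney = 23),
                       comparisons = list(
                         list(test = "ATRT", ref = "brain"),
                         list(test = "KRT", ref = "kidney"),
                         list(test = "KRT", ref = "ATRT")
                       ),
                       baseline_mean = 7,
                       baseline_sd = 0.7,
                       gene_mean_sd = 1.5,
                       de_effect = 2,
                       n_de_per_comparison = 30,
                       n_de_lncrna_per_comparison = 6,
                       pair_blocks = data.frame(
                         type = c("I", "II", "III", "IV", "concordant"),
                         count = c(20L, 10L, 4L, 4L, 8L),
                         target_pcc = 0.9
                       ),
                       pair_comparison = 1L,
                       n_markers = 2,
                       marker_separation = 5,
                       marker_degree = 10,
                       marker_pair_pcc = 0.9,
                       n_cancer_decoys = 8,
                       dataset_offsets = c(d1 = 0),
                       seed = 1L) {
  cfg <- list(
    n_pcg = n_pcg, n_lncrna = n_lncrna, n_housekeeping = n_housekeeping,
    group_sizes = group_sizes, comparisons = comparisons,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    gene_mean_sd = gene_mean_sd, de_effect = de_effect,
    n_de_per_comparison = n_de_per_comparison,
    n_de_lncrna_per_comparison = n_de_lncrna_per_comparison,
    pair_blocks = pair_blocks, pair_comparison = as.integer(pair_comparison),
    n_markers = n_markers, marker_separation = marker_separation,
    marker_degree = marker_degree, marker_pair_pcc = marker_pair_pcc,
    n_cancer_decoys = n_cancer_decoys, dataset_offsets = dataset_offsets,
    seed = as.integer(seed)
  )
  if (!is.data.frame(cfg$pair_blocks))  # e.g. parsed from YAML
    cfg$pair_blocks <- rbind_list(lapply(cfg$pair_blocks, as.data.frame))
  pair_blocks <- cfg$pair_blocks
  if (is.list(cfg$group_sizes)) cfg$group_sizes <- unlist(cfg$group_sizes)
  if (is.list(cfg$dataset_offsets)) cfg$dataset_offsets <- unlist(cfg$dataset_offsets)
  group_sizes <- cfg$group_sizes; dataset_offsets <- cfg$dataset_offsets
  for (f in c("n_pcg", "n_lncrna", "n_housekeeping", "n_de_per_comparison",
              "n_de_lncrna_per_comparison", "n_markers", "marker_degree",
              "n_cancer_decoys"))
    assert_that(is_count(cfg[[f]]), "%s must be a non-negative integer", f)
  assert_that(length(group_sizes) >= 1L && !is.null(names(group_sizes)),
              "group_sizes must be a named vector")
  assert_that(all(group_sizes >= 3), "every group size must be >= 3")
  assert_that(baseline_sd > 0 && gene_mean_sd >= 0, "noise scales must be positive")
  conds <- names(group_sizes)
  for (cmp in comparisons)
    assert_that(all(c(cmp$test, cmp$ref) %in% conds),
                "comparison refers to unknown condition: %s vs %s", cmp$test, cmp$ref)
  assert_that(is.data.frame(pair_blocks) &&
                all(c("type", "count", "target_pcc") %in% names(pair_blocks)),
              "pair_blocks needs columns type, count, target_pcc")
  assert_that(all(pair_blocks$type %in% c("I", "II", "III", "IV", "concordant")),
              "pair_blocks$type must be I/II/III/IV/concordant")
  assert_that(all(pair_blocks$count >= 0) &&
                all(pair_blocks$target_pcc > 0 & pair_blocks$target_pcc < 1),
              "pair_blocks: counts >= 0 and target_pcc in (0,1)")
  assert_that(is_prob(marker_pair_pcc), "marker_pair_pcc must be in (0,1)")
  assert_that(cfg$pair_comparison >= 1L && cfg$pair_comparison <= length(comparisons),
              "pair_comparison out of range")
  assert_that(!is.null(names(dataset_offsets)), "dataset_offsets must be named")

  n_block_pairs <- sum(pair_blocks$count)
  need_pcg <- n_markers + n_cancer_decoys +
    length(comparisons) * n_de_per_comparison + n_block_pairs
  assert_that(need_pcg <= n_pcg,
              "infeasible config: %d PCGs required for planted structure but n_pcg = %d",
              need_pcg, n_pcg)
  need_lnc <- n_markers * marker_degree + n_block_pairs +
    length(comparisons) * n_de_lncrna_per_comparison
  assert_that(need_lnc <= n_lncrna,
              "infeasible config: %d lncRNAs required for planted structure but n_lncrna = %d",
              need_lnc, n_lncrna)
  structure(cfg, class = "sim_config")
}

comparison_label <- function(cmp) paste0(cmp$test, "_vs_", cmp$ref)

#' Theoretical AUC of a binormal marker
#'
#' Closed-form AUC for two equal-variance normal classes separated by a
#' standardized mean difference: `pnorm(separation / sqrt(2))`. Used to
#' calibrate the empirical AUC of simulated markers.
#'
#' @param separation Delta/sigma, the between-class mean difference in
#'   within-class standard-deviation units.
#' @return probability in \[0.5, 1\] for non-negative separations (symmetric
#'   below 0.5 for negative ones).
#' @export
theoretical_auc <- function(separation) {
  assert_that(is.numeric(separation), "separation must be numeric")
  stats::pnorm(separation / sqrt(2))
}

#' Simulate an expression dataset with known ground truth
#'
#' Generates a log2 expression matrix with the structure every downstream
#' stage assumes — group-specific means, planted fold changes, planted
#' lncRNA-PCG co-expression blocks of each dysregulation type, hub marker
#' genes with specified class separation, stable housekeeping genes, and
#' additive dataset-level offsets — together with a ground-truth manifest for
#' parameter-recovery tests.
#'
#' Correlated pairs are built from a shared standard-normal latent factor with
#' loading `sqrt(target_pcc)` on each member, giving a population correlation
#' of exactly `target_pcc`; marker hubs share one factor per tumor condition
#' with all of their partners.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (an `expression_dataset`) and `truth`
#'   (list: `de_genes`, `planted_pairs`, `marker_genes`, `housekeeping_ids`,
#'   `cancer_decoys`, `dataset_offsets`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  assert_that(inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  conds <- names(cfg$group_sizes)
  n_samp <- sum(cfg$group_sizes)
  sample_id <- sprintf("S%03d", seq_len(n_samp))
  condition <- rep(conds, cfg$group_sizes)
  # round-robin dataset assignment within each condition
  ds_names <- names(cfg$dataset_offsets)
  dataset_id <- unlist(lapply(cfg$group_sizes, function(n)
    rep_len(ds_names, n)), use.names = FALSE)
  metadata <- data.frame(sample_id = sample_id, condition = condition,
                         dataset_id = dataset_id, stringsAsFactors = FALSE)

  pcg <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  lnc <- sprintf("LNC%04d", seq_len(cfg$n_lncrna))
  hk <- if (cfg$n_housekeeping > 0) sprintf("HK%04d", seq_len(cfg$n_housekeeping)) else character()
  genes <- c(pcg, lnc, hk)
  n_gene <- length(genes)

  # --- role assignment (deterministic, front-to-back) ---------------------
  take <- function(pool, n, used) {
    avail <- setdiff(pool, used)
    avail[seq_len(n)]
  }
  used_pcg <- character(); used_lnc <- character()
  markers <- take(pcg, cfg$n_markers, used_pcg); used_pcg <- c(used_pcg, markers)
  decoys <- take(pcg, cfg$n_cancer_decoys, used_pcg); used_pcg <- c(used_pcg, decoys)
  de_pcg <- list(); de_lnc <- list()
  for (i in seq_along(cfg$comparisons)) {
    de_pcg[[i]] <- take(pcg, cfg$n_de_per_comparison, used_pcg)
    used_pcg <- c(used_pcg, de_pcg[[i]])
    de_lnc[[i]] <- take(lnc, cfg$n_de_lncrna_per_comparison, used_lnc)
    used_lnc <- c(used_lnc, de_lnc[[i]])
  }
  n_block_pairs <- sum(cfg$pair_blocks$count)
  block_pcg <- take(pcg, n_block_pairs, used_pcg); used_pcg <- c(used_pcg, block_pcg)
  block_lnc <- take(lnc, n_block_pairs, used_lnc); used_lnc <- c(used_lnc, block_lnc)
  marker_partners <- list()
  for (m in markers) {
    marker_partners[[m]] <- take(lnc, cfg$marker_degree, used_lnc)
    used_lnc <- c(used_lnc, marker_partners[[m]])
  }

  # --- condition means ----------------------------------------------------
  mu <- stats::rnorm(n_gene, cfg$baseline_mean, cfg$gene_mean_sd)
  names(mu) <- genes
  delta <- matrix(0, n_gene, length(conds), dimnames = list(genes, conds))

  de_rows <- list()
  for (i in seq_along(cfg$comparisons)) {
    cmp <- cfg$comparisons[[i]]
    lab <- comparison_label(cmp)
    ids <- c(de_pcg[[i]], de_lnc[[i]])
    if (length(ids) == 0L) next
    signs <- rep_len(c(1, -1), length(ids))
    delta[ids, cmp$test] <- delta[ids, cmp$test] + signs * cfg$de_effect
    de_rows[[lab]] <- data.frame(
      gene_id = ids, comparison = lab, effect = signs * cfg$de_effect,
      biotype = ifelse(ids %in% pcg, "protein_coding", "lncRNA"),
      stringsAsFactors = FALSE
    )
  }

  # marker mean shifts: full separation in the test condition of comparison 1,
  # half in the test condition of comparison 2 (when distinct)
  t1 <- cfg$comparisons[[1L]]$test
  t2 <- if (length(cfg$comparisons) >= 2L) cfg$comparisons[[2L]]$test else t1
  d1 <- cfg$marker_separation * cfg$baseline_sd
  d2 <- if (identical(t2, t1)) d1 else d1 / 2
  if (length(markers)) {
    delta[markers, t1] <- delta[markers, t1] + d1
    if (!identical(t2, t1)) delta[markers, t2] <- delta[markers, t2] + d2
    for (i in seq_along(cfg$comparisons)) {
      cmp <- cfg$comparisons[[i]]
      eff <- delta[markers[1L], cmp$test] - delta[markers[1L], cmp$ref]
      de_rows[[paste0("mk_", i)]] <- data.frame(
        gene_id = markers, comparison = comparison_label(cmp),
        effect = rep(eff, length(markers)), biotype = "protein_coding",
        stringsAsFactors = FALSE
      )
    }
  }

  # --- standardized residuals with planted correlation --------------------
  cond_cols <- lapply(conds, function(cc) which(condition == cc))
  names(cond_cols) <- conds
  z <- matrix(stats::rnorm(n_gene * n_samp), n_gene, n_samp,
              dimnames = list(genes, sample_id))

  plant_pair <- function(z, l_id, p_id, cond, sign_p, pcc) {
    cols <- cond_cols[[cond]]
    lam <- sqrt(pcc)
    f <- stats::rnorm(length(cols))
    z[l_id, cols] <- lam * f + sqrt(1 - pcc) * stats::rnorm(length(cols))
    z[p_id, cols] <- sign_p * lam * f + sqrt(1 - pcc) * stats::rnorm(length(cols))
    z
  }

  pair_rows <- list()
  cmp_b <- cfg$comparisons[[cfg$pair_comparison]]
  lab_b <- comparison_label(cmp_b)
  k <- 0L
  for (b in seq_len(nrow(cfg$pair_blocks))) {
    type <- cfg$pair_blocks$type[b]
    pcc <- cfg$pair_blocks$target_pcc[b]
    cnt <- cfg$pair_blocks$count[b]
    if (cnt == 0L) next
    for (j in seq_len(cnt)) {
      k <- k + 1L
      l_id <- block_lnc[k]; p_id <- block_pcg[k]
      # states under reference-first orientation for the block comparison
      st <- switch(type,
        I = c(ref = "positive", test = "absent"),
        II = c(ref = "absent", test = "positive"),
        III = c(ref = "positive", test = "negative"),
        IV = c(ref = "negative", test = "positive"),
        concordant = c(ref = "positive", test = "positive")
      )
      for (side in c("ref", "test")) {
        if (st[[side]] == "absent") next
        z <- plant_pair(z, l_id, p_id, cmp_b[[side]],
                        if (st[[side]] == "positive") 1 else -1, pcc)
      }
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        lncrna_id = l_id, pcg_id = p_id, comparison = lab_b, true_type = type,
        state_ref = st[["ref"]], state_test = st[["test"]],
        target_pcc = pcc, stringsAsFactors = FALSE
      )
    }
  }

  # marker hubs: one latent factor per (marker, tumor condition), partners
  # split flip / first-tumor-only / second-tumor-only
  lam_m <- sqrt(cfg$marker_pair_pcc)
  for (m in markers) {
    partners <- marker_partners[[m]]
    d <- length(partners)
    n_flip <- d %/% 2L
    roles <- c(rep("flip", n_flip), rep_len(c("t1", "t2"), d - n_flip))
    f_cond <- list()
    for (cc in unique(c(t1, t2))) {
      cols <- cond_cols[[cc]]
      f_cond[[cc]] <- stats::rnorm(length(cols))
      z[m, cols] <- lam_m * f_cond[[cc]] +
        sqrt(1 - cfg$marker_pair_pcc) * stats::rnorm(length(cols))
    }
    # per-partner sign of correlation in each tumor condition (0 = absent)
    sign_in <- function(role, cc) {
      if (role == "flip") return(if (cc == t1) 1 else -1)
      if (role == "t1") return(if (cc == t1) 1 else 0)
      if (cc == t2) 1 else 0
    }
    for (j in seq_len(d)) {
      l_id <- partners[j]
      for (cc in unique(c(t1, t2))) {
        s <- sign_in(roles[j], cc)
        if (s == 0) next
        cols <- cond_cols[[cc]]
        z[l_id, cols] <- s * lam_m * f_cond[[cc]] +
          sqrt(1 - cfg$marker_pair_pcc) * stats::rnorm(length(cols))
      }
      # ground-truth dysregulation type of this pair in every comparison
      state_in <- function(cc) {
        s <- if (cc %in% c(t1, t2)) sign_in(roles[j], cc) else 0
        c("negative", "absent", "positive")[s + 2L]
      }
      for (i in seq_along(cfg$comparisons)) {
        cmp <- cfg$comparisons[[i]]
        s_ref <- state_in(cmp$ref); s_test <- state_in(cmp$test)
        ty <- classify_pair(s_ref, s_test, orientation = "table")
        if (!ty %in% c("I", "II", "III", "IV")) next
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          lncrna_id = l_id, pcg_id = m, comparison = comparison_label(cmp),
          true_type = ty, state_ref = s_ref, state_test = s_test,
          target_pcc = cfg$marker_pair_pcc, stringsAsFactors = FALSE
        )
      }
    }
  }

  # --- assemble matrix ----------------------------------------------------
  offsets <- cfg$dataset_offsets[metadata$dataset_id]
  exprs <- mu + delta[, condition, drop = FALSE] + cfg$baseline_sd * z
  exprs <- sweep(exprs, 2L, offsets, "+")
  dimnames(exprs) <- list(genes, sample_id)

  annotation <- data.frame(
    gene_id = genes,
    biotype = c(rep("protein_coding", length(pcg)), rep("lncRNA", length(lnc)),
                rep("protein_coding", length(hk))),
    is_cancer_gene = genes %in% c(markers, decoys),
    is_housekeeping = genes %in% hk,
    length_nt = c(sample(500:10000, length(pcg), replace = TRUE),
                  sample(300:5000, length(lnc), replace = TRUE),
                  sample(500:10000, length(hk), replace = TRUE)),
    stringsAsFactors = FALSE
  )

  dataset <- assemble_dataset(exprs, annotation, metadata)
  truth <- list(
    de_genes = rbind_list(de_rows),
    planted_pairs = rbind_list(pair_rows),
    marker_genes = if (length(markers)) data.frame(
      gene_id = markers,
      separation = cfg$marker_separation,
      theoretical_auc = theoretical_auc(cfg$marker_separation),
      stringsAsFactors = FALSE
    ) else NULL,
    housekeeping_ids = hk,
    cancer_decoys = decoys,
    dataset_offsets = cfg$dataset_offsets,
    config = cfg
  )
  list(dataset = dataset, truth = truth)
}
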