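#' Classify a pair-state transition between two conditions
#'
#' Maps the presence states of one lncRNA-PCG pair in a reference and a test
#' condition onto the four-type dysregulation taxonomy:
#'
#' * `none` — absent in both conditions;
#' * `concordant` — co-expressed with the same sign in both (not counted as
#'   dysregulated);
#' * presence flips (`I`/`II`) — co-expressed in exactly one condition;
#' * sign flips (`III`/`IV`) — co-expressed in both with opposite signs.
#'
#' Two orientation conventions are supported because the published table
#' layout and its caption disagree. Under `"table"` (default,
#' reference-condition-first): type I is present in the reference and absent
#' in the test condition, type III positive in the reference and negative in
#' the test. Under `"caption"` the roles are swapped (I <-> II, III <-> IV).
#'
#' @param state_ref,state_test vectors of states in
#'   `{"absent", "positive", "negative"}`.
#' @param orientation `"table"` or `"caption"`.
#' @return character vector over
#'   `{"none", "concordant", "I", "II", "III", "IV"}`.
#' @export
classify_pair <- function(state_ref, state_test, orientation = c("table", "caption")) {
  orientation <- match.arg(orientation)
  states <- c("absent", "positive", "negative")
  assert_that(all(state_ref %in% states) && all(state_test %in% states),
              "states must be absent/positive/negative")
  out <- character(length(state_ref))
  ref_abs <- state_ref == "absent"; test_abs <- state_test == "absent"
  out[ref_abs & test_abs] <- "none"
  out[!ref_abs & !test_abs & state_ref == state_test] <- "concordant"
  out[!ref_abs & test_abs] <- "I"
  out[ref_abs & !test_abs] <- "II"
  out[state_ref == "positive" & state_test == "negative"] <- "III"
  out[state_ref == "negative" & state_test == "positive"] <- "IV"
  if (orientation == "caption") {
    swap <- c(I = "II", II = "I", III = "IV", IV = "III")
    idx <- out %in% names(swap)
    out[idx] <- swap[out[idx]]
  }
  out
}

#' Type the dysregulated pairs of one comparison
#'
#' Joins the per-condition pair tables of a (reference, test) comparison over
#' their common pair universe, classifies every pair with [classify_pair()],
#' and returns the dysregulated ones (types I-IV; `none` and `concordant`
#' pairs are excluded).
#'
#' @param pairs_ref,pairs_test `pair_table`s from [build_pair_network()] over
#'   the same pair universe and cutoffs.
#' @param orientation see [classify_pair()].
#' @return data.frame of class `typed_pairs`: `lncrna_id`, `pcg_id`,
#'   `ref_condition`, `test_condition`, `state_ref`, `state_test`, `dys_type`.
#' @export
type_pairs <- function(pairs_ref, pairs_test, orientation = c("table", "caption")) {
  orientation <- match.arg(orientation)
  key_ref <- paste(pairs_ref$lncrna_id, pairs_ref$pcg_id, sep = "\r")
  key_test <- paste(pairs_test$lncrna_id, pairs_test$pcg_id, sep = "\r")
  if (!setequal(key_ref, key_test) || anyDuplicated(key_ref) || anyDuplicated(key_test)) {
    diff <- c(setdiff(key_ref, key_test), setdiff(key_test, key_ref))
    stop_rm("pair universes differ between conditions (%d mismatching pairs, e.g. %s)",
            length(diff), paste(utils::head(gsub("\r", "/", diff), 3), collapse = ", "))
  }
  ord <- match(key_ref, key_test)
  dys_type <- classify_pair(pairs_ref$state, pairs_test$state[ord], orientation)
  keep <- dys_type %in% c("I", "II", "III", "IV")
  out <- data.frame(
    lncrna_id = pairs_ref$lncrna_id[keep],
    pcg_id = pairs_ref$pcg_id[keep],
    ref_condition = rep(pairs_ref$condition[1L] %||% NA_character_, sum(keep)),
    test_condition = rep(pairs_test$condition[1L] %||% NA_character_, sum(keep)),
    state_ref = pairs_ref$state[keep],
    state_test = pairs_test$state[ord][keep],
    dys_type = dys_type[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("typed_pairs", "data.frame")
  attr(out, "orientation") <- orientation
  out
}

#' Count dysregulated pairs by gene tier and type
#'
#' Tabulates the typed pairs of one comparison over nested PCG universes:
#' `AllPCG` (all pairs), `DiffPCG` (pairs whose PCG belongs to the
#' differential set, in the motivating analysis the three-set-overlap PCGs)
#' and `CancerG` (pairs whose PCG belongs to the supplied cancer tier set).
#' The CancerG set is used exactly as given — it is *not* forced to be a
#' subset of DiffPCG, because published tier tables of this kind are not
#' always nested; the pipeline passes the cancer genes among the
#' differential set here, but the contract leaves that to the caller.
#'
#' @param typed a `typed_pairs` table (one comparison).
#' @param diffpcg_set,cancer_gene_set character vectors of PCG ids; either may
#'   be `NULL` to skip its tier.
#' @return data.frame with columns `tier`, `dys_type`, `n_pairs` (all four
#'   types present, zero-filled).
#' @export
count_by_tier <- function(typed, diffpcg_set = NULL, cancer_gene_set = NULL) {
  types <- c("I", "II", "III", "IV")
  tiers <- list(AllPCG = unique(typed$pcg_id))
  if (!is.null(diffpcg_set)) tiers$DiffPCG <- diffpcg_set
  if (!is.null(cancer_gene_set)) tiers$CancerG <- cancer_gene_set
  rows <- list()
  for (tn in names(tiers)) {
    in_tier <- typed$pcg_id %in% tiers[[tn]]
    cnt <- table(factor(typed$dys_type[in_tier], levels = types))
    rows[[tn]] <- data.frame(tier = tn, dys_type = types,
                             n_pairs = as.integer(cnt), stringsAsFactors = FALSE)
  }
  rbind_list(rows)
}

#' Per-tier totals of a type-count table
#'
#' @param counts output of [count_by_tier()] (optionally with extra grouping
#'   columns such as `comparison`).
#' @return data.frame with one row per (grouping, tier) and the summed
#'   `n_pairs`.
#' @export
tier_totals <- function(counts) {
  by_cols <- intersect(c("comparison", "tier"), names(counts))
  stats::aggregate(counts["n_pairs"], counts[by_cols], sum)
}

#' Per-PCG degree over dysregulated pairs
#'
#' Degree of a PCG is the number of distinct lncRNAs it forms dysregulated
#' pairs with in one comparison (partner multiplicity across types is not
#' double-counted).
#'
#' @param typed a `typed_pairs` table from one comparison.
#' @param pcg_universe optional PCG ids to report even when their degree is 0.
#' @return data.frame: `pcg_id`, `degree`.
#' @export
compute_degree <- function(typed, pcg_universe = NULL) {
  if (nrow(typed) == 0L) {
    out <- data.frame(pcg_id = character(), degree = integer(),
                      stringsAsFactors = FALSE)
  } else {
    uniq <- unique(typed[, c("pcg_id", "lncrna_id")])
    tab <- table(uniq$pcg_id)
    out <- data.frame(pcg_id = names(tab), degree = as.integer(tab),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(pcg_universe)) {
    zero <- setdiff(pcg_universe, out$pcg_id)
    out <- rbind(out, data.frame(pcg_id = zero, degree = 0L,
                                 stringsAsFactors = FALSE))
    out <- out[match(pcg_universe, out$pcg_id), , drop = FALSE]
  } else {
    out <- out[order(out$pcg_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Expand a published type-count table into a typed-pair fixture
#'
#' Inverse of [count_by_tier()] for nested tiers: given per-comparison counts
#' of dysregulated pairs by tier and type, constructs a synthetic typed-pair
#' table (with generated gene ids) plus the tier membership sets whose
#' [count_by_tier()] tabulation reproduces the input exactly. Used to check
#' the taxonomy arithmetic against published count tables.
#'
#' @param counts data.frame with columns `comparison`, `tier`
#'   (`AllPCG`/`DiffPCG`/`CancerG`), `dys_type`, `n_pairs`; within each
#'   (comparison, type) no sub-tier may exceed `AllPCG`, but `DiffPCG` and
#'   `CancerG` need not be nested in each other.
#' @return named list (one element per comparison) of lists with `typed`,
#'   `diffpcg_set`, `cancerg_set`.
#' @export
pairs_from_type_counts <- function(counts) {
  req <- c("comparison", "tier", "dys_type", "n_pairs")
  assert_that(all(req %in% names(counts)), "counts needs columns %s",
              paste(req, collapse = ", "))
  out <- list()
  for (cmp in unique(counts$comparison)) {
    sub <- counts[counts$comparison == cmp, , drop = FALSE]
    rows <- list(); diff_set <- character(); cancer_set <- character()
    serial <- 0L
    for (ty in unique(sub$dys_type)) {
      get_n <- function(tier) {
        v <- sub$n_pairs[sub$tier == tier & sub$dys_type == ty]
        if (length(v) == 0L) 0L else as.integer(v)
      }
      n_all <- get_n("AllPCG"); n_diff <- get_n("DiffPCG"); n_cancer <- get_n("CancerG")
      assert_that(n_diff <= n_all && n_cancer <= n_all,
                  "tier counts exceed AllPCG for %s type %s", cmp, ty)
      if (n_all == 0L) next
      ids <- sprintf("%s_%s_P%06d", gsub("[^A-Za-z0-9]", "", cmp), ty,
                     serial + seq_len(n_all))
      serial <- serial + n_all
      # membership with maximal overlap; published tables need not be nested
      diff_set <- c(diff_set, ids[seq_len(n_diff)])
      cancer_set <- c(cancer_set, ids[seq_len(n_cancer)])
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = paste0("L_", ids), pcg_id = ids,
        ref_condition = NA_character_, test_condition = NA_character_,
        state_ref = NA_character_, state_test = NA_character_,
        dys_type = ty, stringsAsFactors = FALSE
      )
    }
    typed <- rbind_list(rows)
    class(typed) <- c("typed_pairs", "data.frame")
    out[[cmp]] <- list(typed = typed, diffpcg_set = diff_set,
                       cancerg_set = cancer_set)
  }
  out
}

#' Bundled dysregulated-pair type counts from the rhabdoid-tumor cohort
#'
#' Per-comparison, per-tier, per-type counts of dysregulated lncRNA-PCG pairs
#' as published for the AT/RT-vs-brain, KRT-vs-kidney and AT/RT-vs-KRT
#' comparisons of the motivating cohort (the "Type I-IV" table). Used as a
#' fixture for taxonomy arithmetic checks.
#'
#' @return data.frame: `comparison`, `tier`, `dys_type`, `n_pairs`.
#' @export
rhabdoid_type_counts <- function() {
  path <- system.file("extdata", "pair_type_counts_rt_cohort.tsv",
                      package = "rhabdomark", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled candidate-gene degree table from the rhabdoid-tumor cohort
#'
#' Degrees (distinct dysregulated lncRNA partners) of the 19 cancer-related
#' candidate PCGs in each of the three cohort comparisons, as published. One
#' cell (ZMYM2 in the AT/RT-vs-KRT comparison) was unreadable in the source
#' table; it is shipped as the smallest value consistent with the published
#' candidate selection and flagged in the `synthetic` column.
#'
#' @return data.frame: `gene_id`, `comparison`, `degree`, `synthetic`.
#' @export
rhabdoid_candidate_degrees <- function() {
  path <- system.file("extdata", "candidate_degrees_rt_cohort.tsv",
                      package = "rhabdomark", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
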