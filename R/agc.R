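#' Housekeeping-gene centering across datasets (AGC scaling)
#'
#' Cross-dataset centering in the Array Generation based gene Centering
#' spirit: every dataset is shifted by an additive log2 factor derived from a
#' shared set of housekeeping genes,
#' `factor_d = mean(HK pooled over all datasets) - mean(HK in dataset d)`,
#' so that after scaling the housekeeping grand means agree across datasets
#' while all within-dataset gene differences are preserved exactly. The
#' operation is idempotent (rescaling yields factors of 0).
#'
#' @param x either a single `expression_dataset` whose metadata `dataset_id`
#'   column marks the source batches, or a named list of `expression_dataset`
#'   objects.
#' @param housekeeping_ids gene ids used as the scaling anchor; defaults to
#'   the genes flagged `is_housekeeping` in the annotation. Only genes present
#'   in every dataset are used; none shared is an error.
#' @return list with `scaled` (same shape as `x`, matrices shifted) and
#'   `factors` (data.frame `dataset_id`, `factor`, `n_housekeeping`).
#' @export
agc_scale <- function(x, housekeeping_ids = NULL) {
  if (inherits(x, "expression_dataset")) {
    validate_dataset(x)
    ids <- unique(x$metadata$dataset_id)
    mats <- lapply(ids, function(d)
      x$exprs[, x$metadata$sample_id[x$metadata$dataset_id == d], drop = FALSE])
    names(mats) <- ids
    hk <- housekeeping_ids %||% hk_ids(x)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "expression_dataset"))) {
    assert_that(!is.null(names(x)), "list of datasets must be named")
    lapply(x, validate_dataset)
    mats <- lapply(x, `[[`, "exprs")
    hk <- housekeeping_ids %||% unique(unlist(lapply(x, hk_ids)))
  } else {
    stop_rm("x must be an expression_dataset or a named list of them")
  }
  assert_that(length(hk) > 0L, "no housekeeping genes given or annotated")
  shared <- Reduce(intersect, lapply(mats, rownames))
  hk <- intersect(hk, shared)
  assert_that(length(hk) > 0L, "no shared housekeeping genes across datasets")

  hk_cells <- lapply(mats, function(m) as.vector(m[hk, , drop = FALSE]))
  pooled <- mean(unlist(hk_cells))
  factors <- vapply(hk_cells, function(v) pooled - mean(v), numeric(1))

  factors_df <- data.frame(dataset_id = names(mats), factor = unname(factors),
                           n_housekeeping = length(hk), stringsAsFactors = FALSE)
  if (inherits(x, "expression_dataset")) {
    shift <- factors[x$metadata$dataset_id]
    x$exprs <- sweep(x$exprs, 2L, shift, "+")
    scaled <- x
  } else {
    scaled <- Map(function(ds, f) { ds$exprs <- ds$exprs + f; ds }, x, factors)
  }
  list(scaled = scaled, factors = factors_df)
}

#' Cross-dataset fold change after AGC scaling
#'
#' Linear-scale fold change `2^(mean_a - mean_b)` of one gene between two
#' sample groups (conditions) pooled across AGC-scaled datasets, with a
#' two-sided Welch test on the log2 values.
#'
#' @param dataset an `expression_dataset` (typically the `scaled` output of
#'   [agc_scale()]); group membership is read from the `condition` column.
#' @param gene_id gene to compare.
#' @param group_a,group_b condition labels; the fold change is group a over
#'   group b (swapping the groups inverts it).
#' @return list: `fold_change`, `log2fc`, `statistic`, `df`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
cross_dataset_fold_change <- function(dataset, gene_id, group_a, group_b) {
  validate_dataset(dataset)
  assert_that(gene_id %in% rownames(dataset$exprs), "gene '%s' not in dataset", gene_id)
  xa <- dataset$exprs[gene_id, condition_samples(dataset, group_a)]
  xb <- dataset$exprs[gene_id, condition_samples(dataset, group_b)]
  lfc <- log2_fold_change(xa, xb)
  tt <- welch_t(xa, xb)
  list(fold_change = 2^lfc, log2fc = lfc, statistic = tt$statistic,
       df = tt$df, p_value = tt$p_value, n_a = length(xa), n_b = length(xb))
}
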