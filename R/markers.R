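#' Three-set gene intersection with Venn regions
#'
#' Exact triple intersection of gene sets plus the sizes of all seven
#' exclusive Venn regions (the figure analog of the candidate funnel).
#'
#' @param set_a,set_b,set_c character vectors (duplicates ignored).
#' @param labels length-3 labels for the sets.
#' @return object of class `gene_set_overlap`: list with `members` (sorted
#'   triple intersection), `regions` (named integer vector of the 7 exclusive
#'   region sizes), `labels`.
#' @export
three_set_overlap <- function(set_a, set_b, set_c,
                              labels = c("A", "B", "C")) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  cc <- unique(as.character(set_c))
  universe <- union(union(a, b), cc)
  in_a <- universe %in% a; in_b <- universe %in% b; in_c <- universe %in% cc
  regions <- c(
    sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c), sum(!in_a & !in_b & in_c),
    sum(in_a & in_b & !in_c), sum(in_a & !in_b & in_c), sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c)
  )
  names(regions) <- c(
    paste0(labels[1], "_only"), paste0(labels[2], "_only"), paste0(labels[3], "_only"),
    paste(labels[1], labels[2], sep = "&"), paste(labels[1], labels[3], sep = "&"),
    paste(labels[2], labels[3], sep = "&"),
    paste(labels, collapse = "&")
  )
  structure(list(members = sort(universe[in_a & in_b & in_c]),
                 regions = regions, labels = labels),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf("three-set overlap of (%s): %d genes in all three sets\n",
              paste(x$labels, collapse = ", "), length(x$members)))
  print(x$regions)
  invisible(x)
}

overlap_members <- function(x) {
  if (inherits(x, "gene_set_overlap")) x$members else unique(as.character(x))
}

#' Select candidate diagnostic markers
#'
#' The candidate funnel: genes that are differentially expressed in all three
#' comparisons (the three-set overlap), belong to the cancer-gene list, and
#' carry dysregulated co-expression pairs in all three comparisons. Each
#' candidate is annotated with its per-comparison degree.
#'
#' @param overlap three-set overlap of DE genes (a `gene_set_overlap` or a
#'   character vector).
#' @param cancer_genes cancer-gene list (character vector or
#'   `gene_set_overlap`).
#' @param dysregulated_cancer_overlap cancer genes dysregulated in all three
#'   comparisons (character vector or `gene_set_overlap`).
#' @param degrees optional long data.frame `gene_id`, `comparison`, `degree`
#'   (e.g. stacked [compute_degree()] outputs); degrees absent for a
#'   candidate/comparison are treated as 0 with a warning.
#' @return data.frame of class `candidate_table`: `gene_id`,
#'   `in_three_set_overlap`, `is_cancer_gene`, one `degree_<comparison>`
#'   column per comparison present in `degrees`, `passes_degree_filter`
#'   (NA until [degree_filter()] is applied).
#' @export
select_candidates <- function(overlap, cancer_genes, dysregulated_cancer_overlap,
                              degrees = NULL) {
  ids <- Reduce(intersect, list(overlap_members(overlap),
                                overlap_members(cancer_genes),
                                overlap_members(dysregulated_cancer_overlap)))
  ids <- sort(ids)
  out <- data.frame(gene_id = ids,
                    in_three_set_overlap = rep(TRUE, length(ids)),
                    is_cancer_gene = rep(TRUE, length(ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(degrees) && nrow(out) > 0L) {
    assert_that(all(c("gene_id", "comparison", "degree") %in% names(degrees)),
                "degrees needs columns gene_id, comparison, degree")
    for (cmp in unique(degrees$comparison)) {
      sub <- degrees[degrees$comparison == cmp, , drop = FALSE]
      d <- sub$degree[match(out$gene_id, sub$gene_id)]
      if (anyNA(d)) {
        warn_rm("no degree for %d candidate(s) in comparison %s; treated as 0",
                sum(is.na(d)), cmp)
        d[is.na(d)] <- 0L
      }
      out[[paste0("degree_", cmp)]] <- as.integer(d)
    }
  }
  out$passes_degree_filter <- rep(NA, nrow(out))
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Filter candidates by network degree
#'
#' Keeps candidates whose degree is strictly greater than `min_degree` in
#' every comparison ("more than five lncRNA partners" means degree >= 6 under
#' the default). Idempotent; raising `min_degree` never adds a gene.
#'
#' @param candidates a `candidate_table` from [select_candidates()] with
#'   `degree_*` columns.
#' @param min_degree strict lower bound, default 5.
#' @return the filtered `candidate_table`, `passes_degree_filter` set to
#'   `TRUE` on all remaining rows.
#' @export
degree_filter <- function(candidates, min_degree = 5L) {
  deg_cols <- grep("^degree_", names(candidates), value = TRUE)
  assert_that(length(deg_cols) > 0L, "candidates has no degree_* columns")
  if (nrow(candidates) == 0L) {
    candidates$passes_degree_filter <- logical(0)
    return(candidates)
  }
  deg <- as.matrix(candidates[, deg_cols, drop = FALSE])
  pass <- rowSums(deg > min_degree) == length(deg_cols)
  out <- candidates[pass, , drop = FALSE]
  out$passes_degree_filter <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
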