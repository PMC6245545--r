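#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file with gene ids in the first column and a header
#' row of sample ids. All cells must parse as numbers; duplicate gene ids are
#' rejected with the offending id named.
#'
#' @param path file path.
#' @param log2_transform apply `log2(x + 1)` to the parsed values, for inputs
#'   stored on the linear scale. Default `FALSE`: values are assumed to be
#'   log2 already.
#' @return numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  assert_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  assert_that(ncol(tab) >= 2L, "malformed header in %s: need gene id column plus >= 1 sample", path)
  gene_ids <- tab[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  assert_that(length(dup) == 0L, "duplicated gene id(s) in %s: %s",
              path, paste(utils::head(dup, 5), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop_rm("non-numeric cell in %s at gene '%s', sample '%s': '%s'",
              path, gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
              vals[bad[1L, 1L], bad[1L, 2L]])
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  if (log2_transform) {
    assert_that(all(is.na(num) | num >= 0), "log2_transform requires non-negative values")
    num <- log2(num + 1)
  }
  num
}

#' Write a log2 expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: round-trips values to full double
#' precision (15 significant digits) and preserves row/column order.
#'
#' @param exprs numeric matrix with dimnames.
#' @param path output file path.
#' @param id_column header name of the gene id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(exprs, path, id_column = "gene_id") {
  df <- data.frame(rownames(exprs), format(exprs, digits = 15, trim = TRUE,
                                           scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(exprs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Columns: `gene_id`, `biotype`, `is_cancer_gene`, `is_housekeeping` and
#' optionally `length_nt`. Booleans accept `0/1/true/false`. Validation rules
#' are those of [validate_gene_annotation()].
#'
#' @inheritParams validate_gene_annotation
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_gene_annotation <- function(path, allow_other = FALSE) {
  assert_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  validate_gene_annotation(tab, allow_other = allow_other)
}

#' Read a sample metadata table from TSV
#'
#' Columns: `sample_id`, `condition`, optional `dataset_id`.
#'
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  validate_sample_metadata(tab)
}

#' Write a generic stage output table to TSV
#'
#' Used by the pipeline for all tabular stage outputs; fixed formatting so
#' identical inputs produce byte-identical files.
#'
#' @param df data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
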