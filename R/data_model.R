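#' Validate a gene annotation table
#'
#' Checks the annotation contract used throughout the pipeline: unique gene
#' ids, known biotypes, boolean cancer-gene and housekeeping flags, and the
#' lncRNA length rule (long non-coding RNAs are non-coding genes longer than
#' 200 nucleotides; shorter entries are structural RNA classes and are not
#' admitted as lncRNAs).
#'
#' @param annotation data.frame with columns `gene_id`, `biotype`
#'   (`protein_coding`, `lncRNA` or `other`), `is_cancer_gene`,
#'   `is_housekeeping`, and optionally `length_nt`.
#' @param allow_other if `FALSE` (default) rows with biotype `other` (rRNA,
#'   tRNA, miRNA, snoRNA, ...) are rejected; if `TRUE` they are kept and
#'   simply never enter the lncRNA/PCG universes.
#' @return the validated annotation data.frame (biotype as character,
#'   flags as logical), invisibly usable downstream.
#' @export
validate_gene_annotation <- function(annotation, allow_other = FALSE) {
  req <- c("gene_id", "biotype", "is_cancer_gene", "is_housekeeping")
  missing_cols <- setdiff(req, names(annotation))
  assert_that(length(missing_cols) == 0L,
              "annotation is missing column(s): %s", paste(missing_cols, collapse = ", "))
  annotation$gene_id <- as.character(annotation$gene_id)
  dup <- unique(annotation$gene_id[duplicated(annotation$gene_id)])
  assert_that(length(dup) == 0L,
              "duplicated gene_id in annotation: %s", paste(utils::head(dup, 5), collapse = ", "))
  known <- c("protein_coding", "lncRNA", "other")
  bad <- setdiff(unique(as.character(annotation$biotype)), known)
  assert_that(length(bad) == 0L,
              "unknown biotype(s): %s (expected %s)", paste(bad, collapse = ", "),
              paste(known, collapse = "/"))
  annotation$biotype <- as.character(annotation$biotype)
  if (!allow_other && any(annotation$biotype == "other")) {
    offending <- annotation$gene_id[annotation$biotype == "other"]
    stop_rm("biotype 'other' not allowed (set allow_other = TRUE to keep): %s",
            paste(utils::head(offending, 5), collapse = ", "))
  }
  annotation$is_cancer_gene <- parse_flag(annotation$is_cancer_gene, "is_cancer_gene")
  annotation$is_housekeeping <- parse_flag(annotation$is_housekeeping, "is_housekeeping")
  if ("length_nt" %in% names(annotation)) {
    len <- annotation$length_nt
    assert_that(all(is.na(len) | (is.finite(len) & len > 0 & len == floor(len))),
                "length_nt must be a positive integer where provided")
    short_lnc <- annotation$biotype == "lncRNA" & !is.na(len) & len <= 200
    assert_that(!any(short_lnc),
                "lncRNA with length_nt <= 200 nt: %s",
                paste(utils::head(annotation$gene_id[short_lnc], 5), collapse = ", "))
  }
  annotation
}

# {0,1,true,false,TRUE,FALSE} -> logical
parse_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x_chr <- tolower(as.character(x))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true")] <- TRUE
  out[x_chr %in% c("0", "false")] <- FALSE
  assert_that(!anyNA(out), "column %s has non-boolean entries", what)
  out
}

#' Validate a sample metadata table
#'
#' @param metadata data.frame with columns `sample_id`, `condition` and
#'   optionally `dataset_id` (source batch label used by AGC scaling; defaults
#'   to a single batch `"d1"`).
#' @return validated data.frame with all three columns as character.
#' @export
validate_sample_metadata <- function(metadata) {
  req <- c("sample_id", "condition")
  missing_cols <- setdiff(req, names(metadata))
  assert_that(length(missing_cols) == 0L,
              "metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  assert_that(length(dup) == 0L,
              "duplicated sample_id in metadata: %s", paste(utils::head(dup, 5), collapse = ", "))
  metadata$condition <- as.character(metadata$condition)
  metadata$dataset_id <- as.character(metadata$dataset_id %||% rep("d1", nrow(metadata)))
  metadata
}

#' Assemble an expression dataset
#'
#' Cross-references a log2 expression matrix with gene annotation and sample
#' metadata into the container consumed by every analysis stage. Genes and
#' samples not present in all inputs are dropped with a warning, or rejected
#' when `strict = TRUE`.
#'
#' @param exprs numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), values on the log2 scale.
#' @param annotation gene annotation table (see [validate_gene_annotation()]).
#' @param metadata sample metadata table (see [validate_sample_metadata()]).
#' @param strict error instead of dropping unmatched genes/samples.
#' @param na_policy `"drop"` removes genes with any missing value (logged via
#'   warning); `"error"` rejects them.
#' @param allow_other passed to [validate_gene_annotation()].
#' @return an object of class `expression_dataset`: a list with elements
#'   `exprs`, `annotation`, `metadata`.
#' @export
assemble_dataset <- function(exprs, annotation, metadata, strict = FALSE,
                             na_policy = c("drop", "error"), allow_other = FALSE) {
  na_policy <- match.arg(na_policy)
  assert_that(is.matrix(exprs) && is.numeric(exprs), "exprs must be a numeric matrix")
  assert_that(!is.null(rownames(exprs)) && !is.null(colnames(exprs)),
              "exprs must have gene ids as rownames and sample ids as colnames")
  annotation <- validate_gene_annotation(annotation, allow_other = allow_other)
  metadata <- validate_sample_metadata(metadata)

  lost_genes <- setdiff(rownames(exprs), annotation$gene_id)
  lost_samples <- setdiff(colnames(exprs), metadata$sample_id)
  if (strict && (length(lost_genes) || length(lost_samples))) {
    stop_rm("strict assembly: %d gene(s) and %d sample(s) missing from annotation/metadata (e.g. %s)",
            length(lost_genes), length(lost_samples),
            paste(utils::head(c(lost_genes, lost_samples), 5), collapse = ", "))
  }
  if (length(lost_genes))
    warn_rm("dropping %d gene(s) without annotation (e.g. %s)",
            length(lost_genes), paste(utils::head(lost_genes, 5), collapse = ", "))
  if (length(lost_samples))
    warn_rm("dropping %d sample(s) without metadata (e.g. %s)",
            length(lost_samples), paste(utils::head(lost_samples, 5), collapse = ", "))

  keep_genes <- intersect(rownames(exprs), annotation$gene_id)
  keep_samples <- intersect(colnames(exprs), metadata$sample_id)
  assert_that(length(keep_genes) > 0L, "no genes shared between matrix and annotation")
  assert_that(length(keep_samples) > 0L, "no samples shared between matrix and metadata")
  exprs <- exprs[keep_genes, keep_samples, drop = FALSE]

  na_genes <- rownames(exprs)[rowSums(is.na(exprs)) > 0L]
  if (length(na_genes)) {
    if (na_policy == "error")
      stop_rm("%d gene(s) contain missing values (e.g. %s)",
              length(na_genes), paste(utils::head(na_genes, 5), collapse = ", "))
    warn_rm("dropping %d gene(s) with missing values (e.g. %s)",
            length(na_genes), paste(utils::head(na_genes, 5), collapse = ", "))
    exprs <- exprs[setdiff(rownames(exprs), na_genes), , drop = FALSE]
  }
  assert_that(nrow(exprs) > 0L, "all genes removed during assembly")

  ds <- structure(
    list(
      exprs = exprs,
      annotation = annotation[match(rownames(exprs), annotation$gene_id), , drop = FALSE],
      metadata = metadata[match(colnames(exprs), metadata$sample_id), , drop = FALSE]
    ),
    class = "expression_dataset"
  )
  rownames(ds$annotation) <- NULL
  rownames(ds$metadata) <- NULL
  validate_dataset(ds)
}

#' Check the internal invariants of an expression dataset
#'
#' Total validator used by tests and stage entry points: matrix/annotation/
#' metadata alignment, absence of missing values, and per-table contracts.
#'
#' @param ds an `expression_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(ds) {
  assert_that(inherits(ds, "expression_dataset"), "not an expression_dataset")
  assert_that(identical(rownames(ds$exprs), ds$annotation$gene_id),
              "matrix rows and annotation are not aligned")
  assert_that(identical(colnames(ds$exprs), ds$metadata$sample_id),
              "matrix columns and metadata are not aligned")
  assert_that(!anyNA(ds$exprs), "expression matrix contains missing values")
  validate_gene_annotation(ds$annotation, allow_other = TRUE)
  validate_sample_metadata(ds$metadata)
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  bt <- table(x$annotation$biotype)
  cond <- table(x$metadata$condition)
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  cat("  biotypes:  ", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  cat("  conditions:", paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  if (length(unique(x$metadata$dataset_id)) > 1L)
    cat("  datasets:  ", paste(unique(x$metadata$dataset_id), collapse = ", "), "\n")
  invisible(x)
}

# Gene-id helpers over the annotated universes.
lnc_ids <- function(ds) ds$annotation$gene_id[ds$annotation$biotype == "lncRNA"]
pcg_ids <- function(ds) ds$annotation$gene_id[ds$annotation$biotype == "protein_coding"]
hk_ids  <- function(ds) ds$annotation$gene_id[ds$annotation$is_housekeeping]

# Samples of one condition, in metadata order.
condition_samples <- function(ds, condition) {
  s <- ds$metadata$sample_id[ds$metadata$condition == condition]
  assert_that(length(s) > 0L, "condition '%s' not present in metadata", condition)
  s
}
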