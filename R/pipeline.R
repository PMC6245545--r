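#' Validate and complete a pipeline configuration
#'
#' Accepts a plain list or a YAML file path, checks it against the pipeline
#' schema, and fills the standard defaults of the target analysis: three
#' comparisons (tumor vs its normal tissue at p = 1e-5, tumor vs tumor at
#' p = 1e-3), fold-change cutoff 2, co-expression cutoffs |PCC| >= 0.7 and
#' p < 0.001, degree filter > 5, reference-first type orientation. Validation
#' problems are aggregated into one error.
#'
#' @param config `NULL` (all defaults, simulated input), a named list, or a
#'   path to a YAML file.
#' @return a `pipeline_config` list with elements `input`, `simulation`,
#'   `comparisons` (each `test`, `ref`, `p_threshold`), `fc_threshold`,
#'   `statistic`, `coexpr`, `type_orientation`, `min_degree`, `roc`,
#'   `out_dir`, `seed`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    assert_that(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  assert_that(is.list(config), "config must be a list or YAML path")

  known <- c("input", "simulation", "comparisons", "fc_threshold", "statistic",
             "coexpr", "type_orientation", "min_degree", "roc", "out_dir", "seed")
  problems <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))

  default_comparisons <- list(
    list(test = "ATRT", ref = "brain", p_threshold = 1e-5),
    list(test = "KRT", ref = "kidney", p_threshold = 1e-5),
    list(test = "KRT", ref = "ATRT", p_threshold = 1e-3)
  )
  out <- list(
    input = config$input,
    simulation = config$simulation %||% list(),
    comparisons = config$comparisons %||% default_comparisons,
    fc_threshold = config$fc_threshold %||% 2,
    statistic = config$statistic %||% "moderated",
    coexpr = list(
      pcc_cutoff = config$coexpr$pcc_cutoff %||% 0.7,
      p_cutoff = config$coexpr$p_cutoff %||% 0.001
    ),
    type_orientation = config$type_orientation %||% "table",
    min_degree = config$min_degree %||% 5,
    roc = list(
      n_boot = config$roc$n_boot %||% 2000,
      level = config$roc$level %||% 0.95
    ),
    out_dir = config$out_dir,
    seed = as.integer(config$seed %||% 1L)
  )

  if (length(out$comparisons) != 3L)
    problems <- c(problems, sprintf(
      "exactly 3 comparisons required for the three-set overlap stage (got %d)",
      length(out$comparisons)))
  for (i in seq_along(out$comparisons)) {
    cmp <- out$comparisons[[i]]
    if (is.null(cmp$test) || is.null(cmp$ref))
      problems <- c(problems, sprintf("comparison %d lacks test/ref", i))
    p <- cmp$p_threshold %||% 1e-5
    if (!is_prob(p, open_high = FALSE))
      problems <- c(problems, sprintf("comparison %d: p_threshold %s out of (0,1]", i, p))
    out$comparisons[[i]]$p_threshold <- p
  }
  if (!(is.numeric(out$fc_threshold) && out$fc_threshold >= 1))
    problems <- c(problems, "fc_threshold must be >= 1")
  if (!out$statistic %in% c("moderated", "welch"))
    problems <- c(problems, "statistic must be 'moderated' or 'welch'")
  if (!is_prob(out$coexpr$pcc_cutoff, open_high = FALSE))
    problems <- c(problems, "coexpr$pcc_cutoff must be in (0,1]")
  if (!is_prob(out$coexpr$p_cutoff))
    problems <- c(problems, "coexpr$p_cutoff must be in (0,1)")
  if (!out$type_orientation %in% c("table", "caption"))
    problems <- c(problems, "type_orientation must be 'table' or 'caption'")
  if (!is_count(out$min_degree))
    problems <- c(problems, "min_degree must be a non-negative integer")
  if (!is_count(out$roc$n_boot, min = 1L))
    problems <- c(problems, "roc$n_boot must be a positive integer")
  if (!is.null(out$input)) {
    need <- c("expression", "annotation", "metadata")
    miss <- setdiff(need, names(out$input))
    if (length(miss))
      problems <- c(problems, sprintf("input lacks path(s): %s",
                                      paste(miss, collapse = ", ")))
  } else {
    # check the simulation arguments eagerly so misconfiguration fails here
    sim_args <- out$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- out$seed
    sim_try <- tryCatch({
      do.call(sim_config, sim_args)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sim_try)) problems <- c(problems, paste("simulation:", sim_try))
  }
  if (length(problems))
    stop_rm("invalid pipeline config:\n  - %s", paste(problems, collapse = "\n  - "))
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the full marker-discovery pipeline
#'
#' Orchestrates the analysis end to end: data ingestion (or simulation), per
#' comparison differential expression, per-condition lncRNA-PCG co-expression
#' networks, four-type dysregulation classification with tier counts and
#' PCG degrees, the three-set-overlap/cancer-gene/degree candidate funnel,
#' ROC evaluation of the final candidates, and housekeeping-gene (AGC)
#' scaling factors when several source datasets are present. Reruns with an
#' identical config and seed produce byte-identical output files.
#'
#' @param config a [validate_config()] input (list, YAML path, or `NULL` for
#'   the all-defaults simulated run).
#' @return (invisibly) a `pipeline_result` list: `report` (the run summary
#'   also serialized to JSON), `tables` (all stage data.frames), `dataset`,
#'   and `truth` (ground-truth manifest when simulated, else `NULL`).
#' @export
run_pipeline <- function(config = NULL) {
  config <- validate_config(config)

  # --- input --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    exprs <- read_expression_matrix(config$input$expression,
                                    log2_transform = isTRUE(config$input$log2_transform))
    ann <- read_gene_annotation(config$input$annotation,
                                allow_other = isTRUE(config$input$allow_other))
    meta <- read_sample_metadata(config$input$metadata)
    dataset <- assemble_dataset(exprs, ann, meta,
                                strict = isTRUE(config$input$strict))
  } else {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    dataset <- sim$dataset
    truth <- sim$truth
  }
  for (cmp in config$comparisons) {
    condition_samples(dataset, cmp$test); condition_samples(dataset, cmp$ref)
  }

  labels <- vapply(config$comparisons, comparison_label, character(1))

  # --- differential expression --------------------------------------------
  de_tables <- list()
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    de_tables[[labels[i]]] <- run_de(
      dataset, cmp$test, cmp$ref,
      de_config(p_threshold = cmp$p_threshold, fc_threshold = config$fc_threshold,
                statistic = config$statistic))
  }

  # --- co-expression networks ---------------------------------------------
  ccfg <- coexpr_config(config$coexpr$pcc_cutoff, config$coexpr$p_cutoff)
  conditions <- unique(unlist(lapply(config$comparisons, function(cmp)
    c(cmp$ref, cmp$test))))
  networks <- lapply(conditions, function(cc)
    build_pair_network(dataset, cc, ccfg))
  names(networks) <- conditions

  # --- dysregulation typing ------------------------------------------------
  typed <- list()
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    typed[[labels[i]]] <- type_pairs(networks[[cmp$ref]], networks[[cmp$test]],
                                     orientation = config$type_orientation)
  }

  # --- candidate funnel -----------------------------------------------------
  de_pcg_sets <- lapply(de_tables, de_genes, biotype = "protein_coding")
  de_lnc_sets <- lapply(de_tables, de_genes, biotype = "lncRNA")
  overlap_pcg <- three_set_overlap(de_pcg_sets[[1]], de_pcg_sets[[2]],
                                   de_pcg_sets[[3]], labels = labels)
  overlap_lnc <- three_set_overlap(de_lnc_sets[[1]], de_lnc_sets[[2]],
                                   de_lnc_sets[[3]], labels = labels)
  cancer_list <- dataset$annotation$gene_id[dataset$annotation$is_cancer_gene]

  counts <- rbind_list(lapply(labels, function(l) {
    ct <- count_by_tier(typed[[l]], diffpcg_set = overlap_pcg$members,
                        cancer_gene_set = intersect(cancer_list,
                                                    overlap_pcg$members))
    cbind(comparison = l, ct, stringsAsFactors = FALSE)
  }))
  degrees <- rbind_list(lapply(labels, function(l) {
    dg <- compute_degree(typed[[l]])
    if (nrow(dg) == 0L) return(NULL)
    data.frame(gene_id = dg$pcg_id, comparison = l, degree = dg$degree,
               stringsAsFactors = FALSE)
  }))
  dys_cancer_sets <- lapply(typed, function(tp)
    intersect(unique(tp$pcg_id), cancer_list))
  dys_cancer_overlap <- three_set_overlap(dys_cancer_sets[[1]],
                                          dys_cancer_sets[[2]],
                                          dys_cancer_sets[[3]], labels = labels)
  candidates <- select_candidates(overlap_pcg, cancer_list, dys_cancer_overlap,
                                  degrees = degrees %||%
                                    data.frame(gene_id = character(),
                                               comparison = character(),
                                               degree = integer()))
  final <- degree_filter(candidates, min_degree = config$min_degree)

  # --- ROC evaluation -------------------------------------------------------
  roc_rows <- list()
  for (g in final$gene_id) {
    for (i in seq_along(config$comparisons)) {
      cmp <- config$comparisons[[i]]
      roc_rows[[paste(g, labels[i])]] <- evaluate_marker(
        dataset, g, cmp$test, cmp$ref,
        n_boot = config$roc$n_boot, level = config$roc$level,
        seed = derive_seed(config$seed, paste0(g, labels[i])))
    }
  }
  roc_table <- rbind_list(roc_rows)

  # --- AGC scaling factors --------------------------------------------------
  agc <- NULL
  if (length(hk_ids(dataset)) > 0L)
    agc <- agc_scale(dataset)

  # --- report ---------------------------------------------------------------
  de_summaries <- lapply(de_tables, function(d) attr(d, "summary"))
  report <- list(
    software = "rhabdomark",
    version = as.character(utils::packageVersion("rhabdomark")),
    seed = config$seed,
    config = list(
      comparisons = config$comparisons, fc_threshold = config$fc_threshold,
      statistic = config$statistic, coexpr = config$coexpr,
      type_orientation = config$type_orientation, min_degree = config$min_degree,
      roc = config$roc
    ),
    n_genes = nrow(dataset$exprs),
    n_samples = ncol(dataset$exprs),
    de_summary = lapply(de_summaries, function(s)
      stats::setNames(as.list(s$n), paste(s$biotype, s$call, sep = "_"))),
    venn = list(pcg = as.list(overlap_pcg$regions),
                lncrna = as.list(overlap_lnc$regions)),
    three_set_overlap = list(pcg = overlap_pcg$members,
                             lncrna = overlap_lnc$members),
    dysregulated_cancer_overlap = dys_cancer_overlap$members,
    type_counts = counts,
    tier_totals = tier_totals(counts),
    n_candidates = nrow(candidates),
    candidates = candidates$gene_id,
    n_final_candidates = nrow(final),
    final_candidates = final$gene_id,
    agc_factors = if (is.null(agc)) NULL else agc$factors
  )

  tables <- list(de = de_tables, networks = networks, typed = typed,
                 type_counts = counts, degrees = degrees,
                 candidates = candidates, final_candidates = final,
                 roc = roc_table,
                 agc_factors = if (is.null(agc)) NULL else agc$factors)

  if (!is.null(config$out_dir))
    write_pipeline_outputs(config$out_dir, tables, report)

  invisible(structure(list(report = report, tables = tables,
                           dataset = dataset, truth = truth),
                      class = "pipeline_result"))
}

# Serialize every stage table as TSV plus the JSON run report.
write_pipeline_outputs <- function(out_dir, tables, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (l in names(tables$de))
    write_stage_table(tables$de[[l]], file.path(out_dir, paste0("de_", l, ".tsv")))
  for (cc in names(tables$networks))
    write_stage_table(tables$networks[[cc]],
                      file.path(out_dir, paste0("pairs_", cc, ".tsv")))
  for (l in names(tables$typed))
    write_stage_table(tables$typed[[l]],
                      file.path(out_dir, paste0("typed_pairs_", l, ".tsv")))
  write_stage_table(tables$type_counts, file.path(out_dir, "type_counts.tsv"))
  if (!is.null(tables$degrees))
    write_stage_table(tables$degrees, file.path(out_dir, "degrees.tsv"))
  write_stage_table(tables$candidates, file.path(out_dir, "candidates.tsv"))
  write_stage_table(tables$final_candidates,
                    file.path(out_dir, "final_candidates.tsv"))
  if (!is.null(tables$roc))
    write_stage_table(tables$roc, file.path(out_dir, "roc_results.tsv"))
  if (!is.null(tables$agc_factors))
    write_stage_table(tables$agc_factors, file.path(out_dir, "agc_factors.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("rhabdomark pipeline run (seed %d): %d genes x %d samples\n",
              r$seed, r$n_genes, r$n_samples))
  cat(sprintf("  three-set overlap: %d PCGs, %d lncRNAs\n",
              length(r$three_set_overlap$pcg), length(r$three_set_overlap$lncrna)))
  cat(sprintf("  candidates: %d -> degree filter -> %d (%s)\n",
              r$n_candidates, r$n_final_candidates,
              paste(r$final_candidates, collapse = ", ")))
  invisible(x)
}
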