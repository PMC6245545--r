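# Independent oracles and small fixture builders used across test files.

# Brute-force AUC: all positive/negative score pairs, ties half-weighted.
oracle_auc <- function(scores, labels) {
  p <- scores[labels]
  n <- scores[!labels]
  grid <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# All permutations of 1:n as a matrix (n rows per column).
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- function(v) {
      if (length(v) == 1L) return(matrix(v, 1L, 1L))
      out <- NULL
      for (i in seq_along(v)) out <- cbind(out, rbind(v[i], rec(v[-i])))
      out
    }
    cache[[key]] <<- rec(seq_len(n))
    cache[[key]]
  }
})

# Exact permutation two-sided p-value for the Pearson correlation.
oracle_perm_pvalue <- function(x, y) {
  n <- length(x)
  P <- all_perms(n)
  r_obs <- cor(x, y)
  xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
  r_perm <- colSums(xs * matrix(ys[P], nrow = n)) / (n - 1)
  mean(abs(r_perm) >= abs(r_obs) - 1e-12)
}

# Deterministic small dataset: one condition pair, hand-built matrices.
tiny_dataset <- function(n_a = 6, n_b = 6, seed = 42) {
  set.seed(seed)
  genes <- c("LNC1", "LNC2", "PCG1", "PCG2", "PCG3", "HK1")
  samples <- sprintf("S%02d", seq_len(n_a + n_b))
  exprs <- matrix(rnorm(length(genes) * length(samples), 7, 0.7),
                  length(genes), dimnames = list(genes, samples))
  annotation <- data.frame(
    gene_id = genes,
    biotype = c("lncRNA", "lncRNA", rep("protein_coding", 4)),
    is_cancer_gene = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_housekeeping = c(rep(FALSE, 5), TRUE),
    length_nt = c(500L, 900L, 1500L, 2000L, 800L, 1200L),
    stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    sample_id = samples,
    condition = rep(c("A", "B"), c(n_a, n_b)),
    dataset_id = "d1",
    stringsAsFactors = FALSE
  )
  assemble_dataset(exprs, annotation, metadata)
}

# Pair table built directly from states, for typing tests.
pair_table_from_states <- function(lnc, pcg, states, condition) {
  data.frame(lncrna_id = lnc, pcg_id = pcg, condition = condition,
             pcc = NA_real_, p_value = NA_real_, n = NA_integer_,
             state = states, degenerate = FALSE, stringsAsFactors = FALSE)
}
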