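#' Co-expression configuration
#'
#' Cutoffs defining a co-expressed lncRNA-PCG pair within one condition:
#' `|PCC| >= pcc_cutoff` together with `p < p_cutoff` (strict/non-strict
#' inequalities exactly as stated).
#'
#' @param pcc_cutoff absolute correlation threshold in (0,1], default 0.7.
#' @param p_cutoff significance level in (0,1), default 0.001.
#' @return a `coexpr_config` list.
#' @export
coexpr_config <- function(pcc_cutoff = 0.7, p_cutoff = 0.001) {
  assert_that(is_prob(pcc_cutoff, open_high = FALSE), "pcc_cutoff must be in (0,1]")
  assert_that(is_prob(p_cutoff), "p_cutoff must be in (0,1)")
  structure(list(pcc_cutoff = pcc_cutoff, p_cutoff = p_cutoff),
            class = "coexpr_config")
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the pipeline's preconditions made
#' explicit (equal lengths >= 3, non-zero variance in both vectors).
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "pearson_r: unequal lengths")
  assert_that(length(x) >= 3L, "pearson_r: need >= 3 observations")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "pearson_r: zero variance input")
  stats::cor(x, y)
}

#' P-value for a Pearson correlation
#'
#' Two-sided test of zero correlation via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom — the de
#' facto standard behind the `P < 0.001` cutoff. `|r| = 1` returns an exact
#' p-value of 0 (perfect fit).
#'
#' @param r correlation(s) in \[-1, 1\] (vectorized).
#' @param n number of samples (>= 3).
#' @return two-sided p-value(s).
#' @export
pcc_pvalue <- function(r, n) {
  assert_that(all(n >= 3), "pcc_pvalue: need n >= 3")
  assert_that(all(abs(r) <= 1 + 1e-12, na.rm = TRUE), "pcc_pvalue: |r| > 1")
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), n - 2)
  p
}

#' Per-condition lncRNA-PCG co-expression pair states
#'
#' Computes the Pearson correlation, its p-value, and the resulting presence
#' state for every (lncRNA, PCG) pair — only cross-biotype pairs are formed —
#' across the samples of one condition. States partition into `positive`
#' (`pcc >= cutoff` and `p < p_cutoff`), `negative` (`pcc <= -cutoff` and
#' `p < p_cutoff`) and `absent`. Genes with zero variance in the condition
#' yield an `absent` state flagged `degenerate`.
#'
#' Pair enumeration is blocked over PCGs so the full AllPCG universe (order
#' 10^6 pairs in the motivating cohort) stays within a bounded memory
#' footprint.
#'
#' @param dataset an `expression_dataset`.
#' @param condition condition label with >= 4 samples.
#' @param config a [coexpr_config()].
#' @param lnc_ids,pcg_ids gene universes; default to all annotated lncRNAs
#'   and protein-coding genes in the dataset.
#' @param block_size number of PCGs correlated per block.
#' @return data.frame of class `pair_table`: `lncrna_id`, `pcg_id`,
#'   `condition`, `pcc`, `p_value`, `n`, `state`, `degenerate`.
#' @export
build_pair_network <- function(dataset, condition, config = coexpr_config(),
                               lnc_ids = NULL, pcg_ids = NULL,
                               block_size = 512L) {
  validate_dataset(dataset)
  assert_that(inherits(config, "coexpr_config"), "config must come from coexpr_config()")
  lnc_ids <- lnc_ids %||% lnc_ids(dataset)
  pcg_ids <- pcg_ids %||% pcg_ids(dataset)
  assert_that(length(lnc_ids) > 0L && length(pcg_ids) > 0L,
              "empty lncRNA or PCG universe")
  assert_that(all(lnc_ids %in% rownames(dataset$exprs)) &&
                all(pcg_ids %in% rownames(dataset$exprs)),
              "gene ids missing from the expression matrix")
  samples <- condition_samples(dataset, condition)
  n <- length(samples)
  assert_that(n >= 4L, "condition '%s' has %d samples; >= 4 required", condition, n)

  xl <- t(dataset$exprs[lnc_ids, samples, drop = FALSE])
  sd_l <- apply(xl, 2L, stats::sd)
  zl <- scale(xl)  # columns with sd 0 become NaN -> NA correlations

  blocks <- split(pcg_ids, ceiling(seq_along(pcg_ids) / block_size))
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    xp <- t(dataset$exprs[blocks[[b]], samples, drop = FALSE])
    zp <- scale(xp)
    r <- crossprod(zl, zp) / (n - 1)  # lnc x pcg correlations
    r[!is.finite(r)] <- NA_real_
    df <- data.frame(
      lncrna_id = rep(lnc_ids, times = ncol(r)),
      pcg_id = rep(blocks[[b]], each = nrow(r)),
      pcc = as.vector(r),
      stringsAsFactors = FALSE
    )
    out[[b]] <- df
  }
  pairs <- rbind_list(out)
  pairs$condition <- condition
  pairs$p_value <- ifelse(is.na(pairs$pcc), NA_real_, pcc_pvalue(pairs$pcc, n))
  pairs$n <- n
  pairs$degenerate <- is.na(pairs$pcc)
  pairs$state <- pair_state(pairs$pcc, pairs$p_value, config)
  pairs <- pairs[, c("lncrna_id", "pcg_id", "condition", "pcc", "p_value",
                     "n", "state", "degenerate")]
  class(pairs) <- c("pair_table", "data.frame")
  attr(pairs, "config") <- config
  pairs
}

# Vectorized state rule; NA correlations (degenerate genes) are absent.
pair_state <- function(pcc, p_value, config) {
  state <- rep("absent", length(pcc))
  sig <- !is.na(pcc) & !is.na(p_value) & p_value < config$p_cutoff
  state[sig & pcc >= config$pcc_cutoff] <- "positive"
  state[sig & pcc <= -config$pcc_cutoff] <- "negative"
  state
}
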