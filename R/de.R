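#' Differential-expression configuration
#'
#' Threshold scheme of the analysis: a raw two-sided p-value cutoff and a
#' linear fold-change cutoff (`fc_threshold = 2` means `|log2FC| >= 1`).
#' P-values are compared unadjusted against `p_threshold`; a BH-FDR column is
#' emitted alongside for transparency but plays no role in the calls.
#'
#' @param p_threshold significance level in (0,1); the tumor-vs-normal
#'   comparisons of the target design use 1e-5, the tumor-vs-tumor comparison
#'   1e-3.
#' @param fc_threshold linear fold change >= 1.
#' @param statistic `"moderated"` (empirical-Bayes shrunken variance, the
#'   default) or `"welch"`.
#' @return a `de_config` list.
#' @export
de_config <- function(p_threshold = 1e-5, fc_threshold = 2,
                      statistic = c("moderated", "welch")) {
  statistic <- match.arg(statistic)
  assert_that(is_prob(p_threshold, open_high = FALSE),
              "p_threshold must be in (0,1]")
  assert_that(is.numeric(fc_threshold) && length(fc_threshold) == 1L && fc_threshold >= 1,
              "fc_threshold must be >= 1")
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 statistic = statistic), class = "de_config")
}

#' Log2 fold change between two groups
#'
#' Difference of group means on the log2 scale (test minus reference), the
#' standard microarray convention for matrices that are already
#' log2-transformed.
#'
#' @param x_test,x_ref non-empty numeric vectors of log2 expression.
#' @return mean(x_test) - mean(x_ref).
#' @export
log2_fold_change <- function(x_test, x_ref) {
  assert_that(length(x_test) > 0L && length(x_ref) > 0L,
              "log2_fold_change: empty group")
  mean(x_test) - mean(x_ref)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs follow explicit conventions:
#' if both groups have zero variance and equal means the gene carries no
#' evidence (`statistic = 0`, `p = 1`); zero variance with unequal means gives
#' `p = 0` flagged `degenerate`.
#'
#' @param x_test,x_ref numeric vectors with >= 2 observations each.
#' @return list with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
welch_t <- function(x_test, x_ref) {
  n1 <- length(x_test); n2 <- length(x_ref)
  assert_that(n1 >= 2L && n2 >= 2L, "welch_t: each group needs >= 2 samples")
  v1 <- stats::var(x_test); v2 <- stats::var(x_ref)
  d <- mean(x_test) - mean(x_ref)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1,
                            degenerate = FALSE))
    return(list(statistic = sign(d) * Inf, df = n1 + n2 - 2, p_value = 0,
                degenerate = TRUE))
  }
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  stat <- d / sqrt(se2)
  list(statistic = stat, df = df, p_value = 2 * stats::pt(-abs(stat), df),
       degenerate = FALSE)
}

# Inverse of the trigamma function by Newton iteration on 1/x-scaled updates.
trigamma_inverse <- function(x) {
  assert_that(is.numeric(x) && length(x) == 1L && x > 0, "trigamma_inverse needs x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior for moderated t-statistics
#'
#' Method-of-moments fit of the scaled inverse chi-square prior
#' `s0^2, d0` to per-gene sample variances, performed on the log scale:
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)` has mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and variance
#' `trigamma(d_g/2) + trigamma(d0/2)`, so `d0` is recovered through the
#' inverse trigamma and `s0^2` from the mean. When the excess variance of
#' `e_g` is non-positive (all gene variances essentially identical),
#' `d0 = Inf` and every gene is assigned the common variance.
#'
#' @param s2 per-gene sample variances (zeros are excluded from the fit).
#' @param df residual degrees of freedom of `s2` (scalar).
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  assert_that(df >= 1, "need >= 1 residual df")
  ok <- is.finite(s2) & s2 > 0
  assert_that(sum(ok) >= 2L, "need >= 2 positive variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-statistics
#'
#' Empirical-Bayes two-group test in the microarray tradition: per-gene pooled
#' variances are shrunken towards a prior estimated from all genes,
#' `s2_tilde = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`, and the resulting
#' t-statistics are referred to a t distribution on `d0 + d_g` degrees of
#' freedom. At `d0 = 0` this reduces to the ordinary pooled-variance t-test;
#' at `d0 = Inf` every gene uses the common variance `s0^2`.
#'
#' @param x numeric matrix, genes x samples.
#' @param groups logical vector (TRUE = test group) or two-level factor whose
#'   first level is the reference, one entry per column of `x`.
#' @param d0_override optional fixed prior df (e.g. `0` or `Inf`) replacing
#'   the estimated one; used for limiting-case checks.
#' @return data.frame with one row per gene: `gene_id`, `statistic`, `df`,
#'   `p_value`; the fitted prior is attached as attributes `d0` and `s02`.
#' @export
moderated_t <- function(x, groups, d0_override = NULL) {
  assert_that(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  if (is.logical(groups)) {
    test <- groups
  } else {
    groups <- as.factor(groups)
    assert_that(nlevels(groups) == 2L, "groups must have exactly two levels")
    test <- groups == levels(groups)[2L]
  }
  assert_that(length(test) == ncol(x), "groups length must match columns of x")
  n1 <- sum(test); n0 <- sum(!test)
  assert_that(n1 >= 2L && n0 >= 2L, "each group needs >= 2 samples")
  assert_that(nrow(x) >= 10L, "moderated_t needs >= 10 genes to estimate the prior")

  m1 <- rowMeans(x[, test, drop = FALSE])
  m0 <- rowMeans(x[, !test, drop = FALSE])
  v1 <- apply(x[, test, drop = FALSE], 1L, stats::var)
  v0 <- apply(x[, !test, drop = FALSE], 1L, stats::var)
  dg <- n1 + n0 - 2L
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / dg

  prior <- if (is.null(d0_override)) {
    estimate_variance_prior(s2, dg)
  } else {
    base <- if (is.finite(d0_override) && d0_override > 0)
      estimate_variance_prior(s2, dg) else
        tryCatch(estimate_variance_prior(s2, dg),
                 error = function(e) list(d0 = NA_real_, s02 = mean(s2)))
    list(d0 = d0_override, s02 = base$s02)
  }
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2)) else
    (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  df_post <- if (is.infinite(prior$d0)) Inf else prior$d0 + dg

  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  stat <- (m1 - m0) / se
  stat[se == 0 & m1 == m0] <- 0
  p <- 2 * stats::pt(-abs(stat), df_post)
  p[stat == 0] <- 1
  out <- data.frame(gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    statistic = stat, df = df_post, p_value = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Two-group differential expression over a dataset
#'
#' Runs the configured statistic for every gene between two conditions,
#' computes log2 fold changes (test minus reference), and calls genes `up`,
#' `down` or `ns` against the raw-p and fold-change thresholds. A biotype
#' summary of the calls (the up/down counts per PCG/lncRNA class) is attached
#' as attribute `summary`.
#'
#' @param dataset an `expression_dataset`.
#' @param condition_test,condition_ref condition labels from the metadata.
#' @param config a [de_config()].
#' @return data.frame of class `de_table`: `gene_id`, `biotype`, `log2fc`,
#'   `statistic`, `df`, `p_value`, `fdr`, `call`; attributes `comparison`,
#'   `summary`, `config`.
#' @export
run_de <- function(dataset, condition_test, condition_ref, config = de_config()) {
  validate_dataset(dataset)
  assert_that(inherits(config, "de_config"), "config must come from de_config()")
  s_test <- condition_samples(dataset, condition_test)
  s_ref <- condition_samples(dataset, condition_ref)
  assert_that(length(s_test) >= 2L && length(s_ref) >= 2L,
              "each condition needs >= 2 samples")
  x <- dataset$exprs[, c(s_ref, s_test), drop = FALSE]
  test <- c(rep(FALSE, length(s_ref)), rep(TRUE, length(s_test)))

  log2fc <- rowMeans(x[, test, drop = FALSE]) - rowMeans(x[, !test, drop = FALSE])
  if (config$statistic == "moderated") {
    res <- moderated_t(x, test)
  } else {
    per_gene <- lapply(seq_len(nrow(x)), function(i)
      welch_t(x[i, test], x[i, !test]))
    res <- data.frame(
      gene_id = rownames(x),
      statistic = vapply(per_gene, `[[`, numeric(1), "statistic"),
      df = vapply(per_gene, `[[`, numeric(1), "df"),
      p_value = vapply(per_gene, `[[`, numeric(1), "p_value"),
      stringsAsFactors = FALSE
    )
  }

  lfc_cut <- log2(config$fc_threshold)
  call <- rep("ns", nrow(res))
  call[res$p_value <= config$p_threshold & log2fc >= lfc_cut] <- "up"
  call[res$p_value <= config$p_threshold & log2fc <= -lfc_cut] <- "down"

  out <- data.frame(
    gene_id = res$gene_id,
    biotype = dataset$annotation$biotype[match(res$gene_id, dataset$annotation$gene_id)],
    log2fc = unname(log2fc),
    statistic = res$statistic,
    df = res$df,
    p_value = res$p_value,
    fdr = stats::p.adjust(res$p_value, method = "BH"),
    call = call,
    stringsAsFactors = FALSE
  )
  class(out) <- c("de_table", "data.frame")
  attr(out, "comparison") <- c(test = condition_test, ref = condition_ref)
  attr(out, "config") <- config
  attr(out, "summary") <- de_summary(out)
  out
}

# Up/down counts split by biotype (the per-comparison DE summary).
de_summary <- function(de) {
  classes <- c("protein_coding", "lncRNA")
  out <- expand.grid(biotype = classes, call = c("up", "down"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(b, cl) sum(de$biotype == b & de$call == cl),
                  out$biotype, out$call)
  out
}

#' Genes called differentially expressed
#'
#' @param de a `de_table` from [run_de()].
#' @param biotype optional biotype filter (`"protein_coding"` or `"lncRNA"`).
#' @return character vector of gene ids with call `up` or `down`.
#' @export
de_genes <- function(de, biotype = NULL) {
  keep <- de$call != "ns"
  if (!is.null(biotype)) keep <- keep & de$biotype == biotype
  de$gene_id[keep]
}
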