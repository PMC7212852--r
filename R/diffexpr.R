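#' Median-ratio normalization
#'
#' Builds a reference profile (per-protein median across all columns, over
#' present values) and rescales each column by the inverse of the median of
#' its ratios to that reference, so every column's median ratio to the
#' reference becomes 1.
#'
#' @param table a `quant_table` (aggregated).
#' @return a `quant_table` with rescaled values; the per-column scale
#'   factors are attached as attribute `"scales"`.
#' @export
median_ratio_normalize <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  ref <- apply(table$values, 1L, stats::median, na.rm = TRUE)
  vals <- table$values
  scales <- numeric(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    r <- vals[, j] / ref
    if (all(is.na(r)))
      stop("column ", table$columns$label[j],
           " shares no proteins with the reference profile")
    scales[j] <- 1 / stats::median(r, na.rm = TRUE)
    vals[, j] <- vals[, j] * scales[j]
  }
  out <- quant_table(vals, table$protein_id, table$gene_symbol,
                     table$species, table$columns)
  attr(out, "scales") <- stats::setNames(scales, table$columns$label)
  out
}

#' Low-quantile imputation of missing abundances
#'
#' Replaces each missing cell by the per-column low quantile (default the
#' 1st percentile) of that column's present values — the usual
#' "missing because below detection" stand-in. Imputed values feed only
#' clustering and heatmaps; differential tests run on observed values.
#'
#' @param table a `quant_table`.
#' @param quantile_prob quantile used for the fill-in value.
#' @return a `quant_table` with no missing cells; logical matrix of imputed
#'   positions attached as attribute `"imputed"`.
#' @export
impute_missing <- function(table, quantile_prob = 0.01) {
  stopifnot(inherits(table, "quant_table"))
  vals <- table$values
  imputed <- is.na(vals)
  for (j in seq_len(ncol(vals))) {
    miss <- imputed[, j]
    if (!any(miss)) next
    present <- vals[!miss, j]
    if (!length(present))
      stop("column ", table$columns$label[j], " is entirely missing")
    vals[miss, j] <- stats::quantile(present, quantile_prob, names = FALSE)
  }
  out <- quant_table(vals, table$protein_id, table$gene_symbol,
                     table$species, table$columns)
  attr(out, "imputed") <- imputed
  out
}

#' Welch's unequal-variance t-test
#'
#' Closed-form Welch statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Missing values are dropped; with fewer than two
#' present values in either group the result is undefined (`NA`s), and such
#' proteins are excluded from multiple-testing correction downstream.
#'
#' @param a,b numeric vectors.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    df <- na + nb - 2
  } else {
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforced and values capped at 1;
#' `NA` p-values are excluded from the correction and stay `NA`. Input order
#' is preserved.
#'
#' @param p numeric vector of p-values in [0, 1] (or `NA`).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Log2 fold change of invasive over core means
#'
#' @param mean_i,mean_a group means over present values.
#' @return `log2(mean_i / mean_a)`, or `NA` if either mean is not positive.
#' @export
log_fold_change <- function(mean_i, mean_a) {
  out <- rep(NA_real_, length(mean_i))
  ok <- !is.na(mean_i) & !is.na(mean_a) & mean_i > 0 & mean_a > 0
  out[ok] <- log2(mean_i[ok] / mean_a[ok])
  out
}

#' Per-protein differential expression between invasive and core
#'
#' Runs Welch's t-test on each protein's observed replicate values
#' (condition I versus A), adjusts p-values by Benjamini-Hochberg within
#' the tested set, computes `log2FC = log2(mean_I / mean_A)` over present
#' values, and sets the three nested hit tiers via [flag_hits()].
#'
#' @param table a `quant_table` (aggregated; normalized recommended).
#' @param config a [pipeline_config()].
#' @return a `de_result` data frame: `protein_id`, `gene_symbol`, `species`,
#'   `mean_A`, `mean_I`, `log2fc`, `t`, `df`, `p`, `padj`, `significant`,
#'   `enrichment_hit`, `clustermap_hit`, `direction`.
#' @export
diff_expr <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "quant_table"))
  selA <- table$columns$condition == "A"
  selI <- table$columns$condition == "I"
  n <- nrow(table$values)
  res <- data.frame(protein_id = table$protein_id,
                    gene_symbol = table$gene_symbol,
                    species = table$species,
                    mean_A = NA_real_, mean_I = NA_real_,
                    log2fc = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- table$values[i, selA]
    b <- table$values[i, selI]
    res$mean_A[i] <- if (any(!is.na(a))) mean(a, na.rm = TRUE) else NA_real_
    res$mean_I[i] <- if (any(!is.na(b))) mean(b, na.rm = TRUE) else NA_real_
    w <- welch_t_test(b, a)  # positive t = invasive-up
    res$t[i] <- w$t; res$df[i] <- w$df; res$p[i] <- w$p
  }
  res$log2fc <- log_fold_change(res$mean_I, res$mean_A)
  res$padj <- bh_adjust(res$p)
  res <- flag_hits(res, config)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Set the nested significance tiers on a DE table
#'
#' `significant`: BH-adjusted p below `padj_threshold`. `enrichment_hit`:
#' significant and |log2FC| above the enrichment gate (1). `clustermap_hit`:
#' significant and |log2FC| above the species-specific clustermap gate
#' (2 human / 5 mouse). For human the tiers are nested:
#' clustermap < enrichment < significant.
#'
#' The described "1.5-fold change with adjusted P below .05" variant is not
#' implemented; `variant_hook` is accepted and ignored so a future rule can
#' slot in without changing call sites.
#'
#' @param results a DE data frame with `padj`, `log2fc`, `species`.
#' @param config a [pipeline_config()].
#' @param variant_hook reserved; ignored.
#' @return `results` with flag columns and `direction` set.
#' @export
flag_hits <- function(results, config = pipeline_config(),
                      variant_hook = NULL) {
  thr <- ifelse(results$species == "mouse",
                config$logfc_clustermap_mouse, config$logfc_clustermap_human)
  sig <- !is.na(results$padj) & results$padj < config$padj_threshold
  results$significant <- sig
  results$enrichment_hit <- sig & !is.na(results$log2fc) &
    abs(results$log2fc) > config$logfc_enrichment
  results$clustermap_hit <- sig & !is.na(results$log2fc) &
    abs(results$log2fc) > thr
  results$direction <- ifelse(is.na(results$log2fc), NA_character_,
                              ifelse(results$log2fc > 0,
                                     "invasive-up", "core-up"))
  results
}

#' Hit counts per species and direction
#'
#' @param results a `de_result`.
#' @return data frame of significant / enrichment / clustermap counts split
#'   by species and direction.
#' @export
de_summary <- function(results) {
  dirs <- c("core-up", "invasive-up")
  sp <- sort(unique(results$species))
  out <- expand.grid(species = sp, direction = dirs,
                     stringsAsFactors = FALSE)
  for (f in c("significant", "enrichment_hit", "clustermap_hit")) {
    out[[f]] <- mapply(function(s, d) {
      sum(results[[f]] & results$species == s &
            !is.na(results$direction) & results$direction == d)
    }, out$species, out$direction)
  }
  out[order(out$species, out$direction), ]
}

#' Volcano-plot table
#'
#' @param results a `de_result`.
#' @return data frame `protein_id`, `gene_symbol`, `log2fc`,
#'   `neg_log10_padj` for external plotting.
#' @export
volcano_table <- function(results) {
  data.frame(protein_id = results$protein_id,
             gene_symbol = results$gene_symbol,
             log2fc = results$log2fc,
             neg_log10_padj = -log10(results$padj),
             stringsAsFactors = FALSE)
}
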