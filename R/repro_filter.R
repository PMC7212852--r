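#' Coefficient of variation of a technical triplicate
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' computed on the present values only. With fewer than two present values
#' the CV is undefined and `NA` is returned (it then contributes nothing to
#' the retention decision).
#'
#' @param values numeric vector of positive abundances, possibly with `NA`.
#' @return scalar CV, or `NA_real_` if fewer than 2 values are present.
#' @export
coefficient_of_variation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  if (any(v <= 0)) stop("abundances must be > 0")
  stats::sd(v) / mean(v)
}

#' Per-triplicate CV report
#'
#' One row per (protein, condition, biological sample) giving the CV over
#' that sample's technical replicates; the histogram source of the
#' reproducibility inspection.
#'
#' @param table a `quant_table`.
#' @return data frame `protein_id`, `condition`, `sample`, `n_present`, `cv`.
#' @export
cv_table <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  grid <- unique(table$columns[, c("condition", "sample")])
  grid <- grid[order(grid$condition, grid$sample), ]
  out <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- table$columns$condition == grid$condition[g] &
      table$columns$sample == grid$sample[g]
    sub <- table$values[, sel, drop = FALSE]
    data.frame(protein_id = table$protein_id,
               condition = grid$condition[g],
               sample = grid$sample[g],
               n_present = rowSums(!is.na(sub)),
               cv = apply(sub, 1L, coefficient_of_variation),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reproducibility filter on technical-replicate CV
#'
#' A protein is retained iff every defined triplicate CV — in both
#' conditions — is strictly below `threshold`. Triplicates with fewer than
#' two present values have no CV and do not veto retention (missingness is
#' handled separately by [aggregate_presence()]).
#'
#' @param table a `quant_table`.
#' @param threshold CV gate, default 0.8.
#' @return list with `table` (retained proteins), `report` (the [cv_table()]
#'   rows plus a `retained` flag), and `retained` (named logical).
#' @export
cv_filter <- function(table, threshold = 0.8) {
  stopifnot(threshold > 0)
  rep_tab <- cv_table(table)
  bad <- tapply(rep_tab$cv >= threshold, rep_tab$protein_id,
                function(z) any(z, na.rm = TRUE))
  retained <- !bad[table$protein_id]
  names(retained) <- table$protein_id
  rep_tab$retained <- retained[rep_tab$protein_id]
  list(table = table[retained, ], report = rep_tab, retained = retained)
}

#' Histogram bins of CV values
#'
#' Binned counts (default width 0.05) per condition and sample, a numeric
#' stand-in for the CV histograms used to pick the reproducibility gate.
#'
#' @param report a [cv_table()] (or `cv_filter()$report`) data frame.
#' @param binwidth bin width.
#' @return data frame `condition`, `sample`, `bin_lo`, `bin_hi`, `count`.
#' @export
cv_histogram <- function(report, binwidth = 0.05) {
  def <- report[!is.na(report$cv), ]
  out <- lapply(split(def, list(def$condition, def$sample), drop = TRUE),
                function(d) {
                  b <- floor(d$cv / binwidth)
                  tb <- table(b)
                  data.frame(condition = d$condition[1], sample = d$sample[1],
                             bin_lo = as.numeric(names(tb)) * binwidth,
                             bin_hi = (as.numeric(names(tb)) + 1) * binwidth,
                             count = as.integer(tb), stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$sample, out$bin_lo), ]
}

#' Presence-based aggregation across samples
#'
#' Keeps a protein iff it is present (non-missing) in at least
#' `presence_min` of the `presence_total` columns of *each* condition, and
#' flags the "common" subset present in every column of every sample.
#'
#' @param table a `quant_table`.
#' @param presence_min minimum present columns per condition (default 6).
#' @param presence_total expected columns per condition (default 9); a
#'   mismatch with the actual design is an error.
#' @return list with `table` (kept proteins), `common` (named logical over
#'   kept proteins), and `presence` (per-protein present counts per
#'   condition).
#' @export
aggregate_presence <- function(table, presence_min = 6L, presence_total = 9L) {
  stopifnot(inherits(table, "quant_table"), presence_min <= presence_total)
  conds <- sort(unique(table$columns$condition))
  counts <- sapply(conds, function(cc) {
    rowSums(!is.na(table$values[, table$columns$condition == cc,
                                drop = FALSE]))
  })
  n_cols <- table(table$columns$condition)
  if (any(n_cols != presence_total))
    stop("presence_total = ", presence_total, " but design has ",
         paste(sprintf("%s:%d", names(n_cols), n_cols), collapse = ", "),
         " columns per condition")
  keep <- apply(counts >= presence_min, 1L, all)
  common_all <- rowSums(!is.na(table$values)) == ncol(table$values)
  kept <- table[keep, ]
  common <- common_all[keep]
  names(common) <- kept$protein_id
  presence <- as.data.frame(counts)
  names(presence) <- paste0("present_", conds)
  presence <- cbind(data.frame(protein_id = table$protein_id,
                               stringsAsFactors = FALSE), presence)
  list(table = kept, common = common, presence = presence)
}
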