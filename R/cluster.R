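#' Ward-D2 hierarchical clustering on Euclidean distances
#'
#' @param mat numeric matrix, items x features, no missing values (impute
#'   first — see [impute_missing()]).
#' @param distance distance metric; only `"euclidean"`.
#' @param linkage linkage criterion; only `"ward-d2"`.
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(mat, distance = "euclidean",
                                 linkage = "ward-d2") {
  distance <- match.arg(distance, "euclidean")
  linkage <- match.arg(linkage, "ward-d2")
  mat <- as.matrix(mat)
  if (anyNA(mat))
    stop("matrix contains missing values; run impute_missing() first")
  if (nrow(mat) < 2L) stop("need at least 2 items to cluster")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("item", seq_len(nrow(mat)))
  stats::hclust(stats::dist(mat, method = "euclidean"), method = "ward.D2")
}

# canonical key for every internal node's member set
hclust_member_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- integer()
    for (child in hc$merge[k, ]) {
      members <- c(members,
                   if (child < 0) -child else attr(sets[[child]], "idx"))
    }
    key <- paste(sort(hc$labels[members]), collapse = "\t")
    sets[[k]] <- key
    attr(sets[[k]], "idx") <- members
  }
  vapply(sets, as.character, "")
}

#' Bootstrap branch support for a Ward-D2 dendrogram
#'
#' Resamples features (columns) with replacement `n_boot` times, re-clusters
#' the items each time, and reports for every internal node of the original
#' dendrogram the bootstrap probability (BP): the percentage of resampled
#' dendrograms containing the same member set. Optionally estimates
#' approximately-unbiased (AU) support by multiscale bootstrap — resample
#' sizes `r * m` for `r` in 0.5..1.4 and a normal-quantile regression
#' `z(r) = v * sqrt(r) + c / sqrt(r)`, `AU = 100 * (1 - pnorm(v - c))`. AU
#' is experimental and off by default; BP is the load-bearing statistic.
#'
#' @param mat numeric matrix, items x features (features >= 2).
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed RNG seed.
#' @param au also estimate AU support (multiplies the cost by the number of
#'   scales).
#' @return list with `hclust` (original tree), `member_sets`, `bp`
#'   (percent per internal node, merge order), and `au` (or `NULL`).
#' @export
bootstrap_support <- function(mat, n_boot = 200L, seed = 1L, au = FALSE) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  mat <- as.matrix(mat)
  m <- ncol(mat)
  if (m < 2L) stop("need at least 2 features to resample")
  hc <- hierarchical_cluster(mat)
  keys <- hclust_member_sets(hc)
  set.seed(as.integer(seed))
  count_hits <- function(size, nb) {
    hits <- numeric(length(keys))
    for (b in seq_len(nb)) {
      idx <- sample.int(m, size, replace = TRUE)
      bk <- hclust_member_sets(hierarchical_cluster(mat[, idx, drop = FALSE]))
      hits <- hits + (keys %in% bk)
    }
    hits / nb
  }
  bp <- 100 * count_hits(m, n_boot)
  au_val <- NULL
  if (au) {
    scales <- seq(0.5, 1.4, by = 0.1)
    bp_r <- sapply(scales, function(r)
      count_hits(max(2L, round(r * m)), n_boot))
    au_val <- vapply(seq_along(keys), function(k) {
      pr <- pmin(pmax(bp_r[k, ], 1 / (n_boot + 1)), n_boot / (n_boot + 1))
      z <- stats::qnorm(1 - pr)
      fit <- stats::lm.fit(cbind(sqrt(scales), 1 / sqrt(scales)), z)
      100 * (1 - stats::pnorm(fit$coefficients[1] - fit$coefficients[2]))
    }, 0)
  }
  list(hclust = hc, member_sets = keys, bp = bp, au = au_val)
}

#' Serialize a dendrogram with support values as Newick
#'
#' Internal node labels carry the rounded support values (e.g. BP percent).
#'
#' @param hc an `hclust`.
#' @param support numeric vector in merge order (as returned by
#'   [bootstrap_support()]), or `NULL` for no labels.
#' @return a single Newick string.
#' @export
dendrogram_newick <- function(hc, support = NULL) {
  phy <- ape::as.phylo(hc)
  if (!is.null(support)) {
    keys <- hclust_member_sets(hc)
    parts <- ape::prop.part(phy)
    node_keys <- vapply(parts, function(idx)
      paste(sort(attr(parts, "labels")[idx]), collapse = "\t"), "")
    phy$node.label <- sprintf("%.4g", support[match(node_keys, keys)])
  }
  ape::write.tree(phy)
}

#' Log2 ratio of each column to the reference profile
#'
#' The reference profile is the per-protein median over all columns of the
#' (complete) matrix; the result feeds sample-level clustering.
#'
#' @param table a `quant_table` without missing values (e.g. the common
#'   subset, or imputed).
#' @return matrix of log2 ratios, proteins x columns.
#' @export
log_ratio_matrix <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (anyNA(table$values))
    stop("log-ratio matrix needs complete values; use the common subset or impute")
  ref <- apply(table$values, 1L, stats::median)
  log2(table$values / ref)
}

#' Clustermap export of the strong differential hits
#'
#' Selects the `clustermap_hit` proteins, z-scores each protein's log2
#' abundances across columns, and clusters both rows (proteins) and columns
#' (replicates) with Ward-D2 on Euclidean distances.
#'
#' @param de a `de_result`.
#' @param table a complete (imputed) `quant_table` containing those proteins.
#' @return list with `matrix` (z-scored, proteins x columns), `row_hclust`,
#'   `col_hclust`; `NULL` (with a warning) when there are no hits.
#' @export
clustermap_export <- function(de, table) {
  hits <- de$protein_id[de$clustermap_hit]
  hits <- intersect(hits, table$protein_id)
  if (!length(hits)) {
    warning("no clustermap hits; empty export")
    return(NULL)
  }
  sub <- table[hits, ]
  lv <- log2(sub$values)
  z <- t(scale(t(lv)))
  z[is.nan(z)] <- 0  # constant rows carry no contrast
  rownames(z) <- sub$protein_id
  row_hc <- if (nrow(z) >= 2L) hierarchical_cluster(z) else NULL
  col_hc <- hierarchical_cluster(t(z))
  list(matrix = z, row_hclust = row_hc, col_hclust = col_hc)
}
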