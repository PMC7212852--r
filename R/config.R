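#' Pipeline configuration
#'
#' Thresholds and knobs for every pipeline stage. Defaults are the values
#' used for the regional core-vs-rim comparison: technical-replicate CV gate
#' at 0.8, presence in at least 6 of 9 columns per condition, differential
#' significance at BH-adjusted p < 0.01, clustermap fold-change gates
#' |log2FC| > 2 (human) and > 5 (mouse), enrichment gate |log2FC| > 1 with
#' adjusted-p 0.05 for over-representation, interaction-network confidence
#' > 0.4, MCL inflation 2, 200 bootstrap resamples.
#'
#' @param cv_threshold CV gate applied per technical triplicate (> 0).
#' @param presence_min minimum non-missing columns per condition.
#' @param presence_total columns per condition in the design.
#' @param padj_threshold BH-adjusted p cutoff for significance.
#' @param logfc_clustermap_human,logfc_clustermap_mouse |log2FC| gates for
#'   the clustermap tier, per species.
#' @param logfc_enrichment |log2FC| gate for the enrichment tier.
#' @param ora_padj adjusted-p cutoff for over-representation calls.
#' @param edge_confidence_min interaction edges kept when confidence is
#'   strictly above this.
#' @param mcl_inflation MCL inflation exponent (> 1 for contraction).
#' @param bootstrap_n dendrogram bootstrap resamples.
#' @param rng_seed seed used by stochastic stages.
#' @return An object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(cv_threshold = 0.8,
                            presence_min = 6L,
                            presence_total = 9L,
                            padj_threshold = 0.01,
                            logfc_clustermap_human = 2,
                            logfc_clustermap_mouse = 5,
                            logfc_enrichment = 1,
                            ora_padj = 0.05,
                            edge_confidence_min = 0.4,
                            mcl_inflation = 2,
                            bootstrap_n = 200L,
                            rng_seed = 1L) {
  cfg <- list(cv_threshold = cv_threshold,
              presence_min = as.integer(presence_min),
              presence_total = as.integer(presence_total),
              padj_threshold = padj_threshold,
              logfc_clustermap_human = logfc_clustermap_human,
              logfc_clustermap_mouse = logfc_clustermap_mouse,
              logfc_enrichment = logfc_enrichment,
              ora_padj = ora_padj,
              edge_confidence_min = edge_confidence_min,
              mcl_inflation = mcl_inflation,
              bootstrap_n = as.integer(bootstrap_n),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("cv_threshold", "padj_threshold", "logfc_clustermap_human",
           "logfc_clustermap_mouse", "logfc_enrichment", "ora_padj",
           "mcl_inflation")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config: ", k, " must be a positive scalar")
  if (cfg$edge_confidence_min < 0 || cfg$edge_confidence_min > 1)
    stop("config: edge_confidence_min must be in [0, 1]")
  if (cfg$presence_min < 1L || cfg$presence_total < 1L)
    stop("config: presence counts must be >= 1")
  if (cfg$presence_min > cfg$presence_total)
    stop("config: presence_min must be <= presence_total")
  if (cfg$bootstrap_n < 1L) stop("config: bootstrap_n must be >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines look like `cv_threshold = 0.8`; blank lines and `#` comments are
#' ignored; unknown keys are an error. Missing keys take their defaults.
#'
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad)) stop("malformed config line: ", bad[1])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(as.numeric(vals)), keys)
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- sprintf("%s = %.6g", names(cfg), as.numeric(unlist(cfg)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
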