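stage_log <- function(stage, species, n_in, n_out) {
  message(sprintf("stage=%s species=%s n_in=%d n_out=%d",
                  stage, species, n_in, n_out))
}

#' Run the full regional-proteomics pipeline
#'
#' Chains the stages in methods order, per species: CV reproducibility
#' filter -> presence aggregation (with the "common" subset) -> median-ratio
#' normalization -> Welch/BH differential expression with tiered flags ->
#' imputation + clustermap and bootstrap-supported sample dendrogram ->
#' over-representation analysis (if a GMT is given) -> confidence-filtered
#' MCL network of the invasive-up hits (if an edge list is given) ->
#' AngioScore comparison of the top core vs invasive hits (if a corpus is
#' given). One structured log line per stage reports the protein funnel;
#' counts never increase along the funnel. All outputs are deterministic
#' TSV/Newick files under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param quant a `quant_table` or path to its TSV.
#' @param out_dir output directory (created).
#' @param species `"human"`, `"mouse"` or `"both"` (stages run per species).
#' @param gmt_path optional GMT gene-set file.
#' @param edges_path optional STRING-style edge list.
#' @param corpus_dir optional publication corpus directory.
#' @param top_n_angio hits per area entering the AngioScore comparison.
#' @return invisibly, a list of per-species result bundles (filter report,
#'   aggregated table, DE table, dendrograms, enrichment, network,
#'   angioscore comparison) plus the funnel counts.
#' @export
run_pipeline <- function(config = pipeline_config(), quant,
                         out_dir, species = "both",
                         gmt_path = NULL, edges_path = NULL,
                         corpus_dir = NULL, top_n_angio = 30L) {
  validate_config(config)
  if (is.character(quant)) quant <- read_quant_table(quant)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_species <- if (species == "both") intersect(c("human", "mouse"),
                                                  unique(quant$species))
                 else species
  sets <- if (!is.null(gmt_path)) read_gmt(gmt_path) else NULL
  graph <- if (!is.null(edges_path)) read_edges(edges_path) else NULL
  corpus <- if (!is.null(corpus_dir)) read_corpus(corpus_dir) else NULL

  results <- list()
  for (sp in run_species) {
    res <- tryCatch(
      run_pipeline_species(config, filter_species(quant, sp), sp, out_dir,
                           sets, graph, corpus, top_n_angio),
      error = function(e) stop("stage failure [species=", sp, "]: ",
                               conditionMessage(e), call. = FALSE))
    results[[sp]] <- res
  }
  invisible(results)
}

run_pipeline_species <- function(config, qt, sp, out_dir, sets, graph,
                                 corpus, top_n_angio) {
  out <- function(name) file.path(out_dir, paste0(sp, "_", name))
  n0 <- nrow(qt$values)

  cvf <- cv_filter(qt, config$cv_threshold)
  stage_log("cv_filter", sp, n0, nrow(cvf$table$values))
  write_table(cvf$report, out("cv_report.tsv"))

  agg <- aggregate_presence(cvf$table, config$presence_min,
                            config$presence_total)
  stage_log("aggregate", sp, nrow(cvf$table$values), nrow(agg$table$values))
  message(sprintf("stage=common species=%s n_common=%d", sp,
                  sum(agg$common)))
  write_quant_table(agg$table, out("aggregated.tsv"))

  norm <- median_ratio_normalize(agg$table)
  de <- diff_expr(norm, config)
  stage_log("diffexp", sp, nrow(norm$values), sum(de$significant))
  de_df <- as.data.frame(de)
  write_table(de_df, out("de_table.tsv"))
  write_table(volcano_table(de), out("volcano.tsv"))
  write_table(de_summary(de), out("de_summary.tsv"))

  imp <- impute_missing(norm)
  cm <- clustermap_export(de, imp)
  if (!is.null(cm)) {
    write_table(cbind(data.frame(protein_id = rownames(cm$matrix),
                                 stringsAsFactors = FALSE),
                      as.data.frame(cm$matrix)), out("clustermap.tsv"))
    if (!is.null(cm$row_hclust))
      writeLines(dendrogram_newick(cm$row_hclust), out("clustermap_rows.nwk"))
    writeLines(dendrogram_newick(cm$col_hclust), out("clustermap_cols.nwk"))
  }

  dendro <- NULL
  common_tab <- agg$table[agg$common, ]
  if (nrow(common_tab$values) >= 2L) {
    lr <- log_ratio_matrix(common_tab)
    dendro <- bootstrap_support(t(lr), n_boot = config$bootstrap_n,
                                seed = config$rng_seed)
    writeLines(dendrogram_newick(dendro$hclust, dendro$bp),
               out("sample_dendrogram.nwk"))
  }

  enr <- NULL
  if (!is.null(sets)) {
    query <- de$gene_symbol[de$enrichment_hit]
    testable <- any(vapply(sets$sets, function(s)
      length(intersect(s, de$gene_symbol)) > 0, TRUE))
    if (!testable)
      message("stage=enrich species=", sp,
              " skipped: no gene set overlaps this species' universe")
    if (length(query) && testable) {
      enr <- ora_test(query, sets, universe = de$gene_symbol,
                      padj_cutoff = config$ora_padj)
      stage_log("enrich", sp, length(query), sum(enr$enriched))
      write_table(enr, out("enrichment.tsv"))
    }
  }

  net <- NULL
  if (!is.null(graph)) {
    inv_genes <- de$gene_symbol[de$significant & !is.na(de$direction) &
                                  de$direction == "invasive-up"]
    sub <- filter_graph(subgraph_nodes(graph, inv_genes),
                        config$edge_confidence_min)
    if (length(sub$nodes) >= 2L) {
      net <- mcl_cluster(sub, inflation = config$mcl_inflation)
      stage_log("network", sp, length(inv_genes), length(net$membership))
      tabs <- mcl_tables(net)
      write_table(tabs$nodes, out("network_clusters.tsv"))
      write_table(tabs$edges, out("network_edges.tsv"))
    }
  }

  angio <- NULL
  if (!is.null(corpus)) {
    sc <- angioscore(corpus)
    core <- top_hits(de, "core-up", top_n_angio)
    inv <- top_hits(de, "invasive-up", top_n_angio)
    scored <- sc$gene[!is.na(sc$angioscore)]
    if (sum(core %in% scored) >= 2L && sum(inv %in% scored) >= 2L) {
      angio <- compare_groups(sc, core, inv, top_n = top_n_angio)
      message(sprintf(
        "stage=angioscore species=%s ratio=%.3f t=%.3f p=%.3g",
        sp, angio$ratio, angio$t, angio$p))
      write_table(sc, out("angioscore.tsv"))
      comp <- data.frame(mean_core = angio$mean_core,
                         mean_invasive = angio$mean_invasive,
                         ratio = angio$ratio, t = angio$t, df = angio$df,
                         p = angio$p)
      write_table(comp, out("angioscore_comparison.tsv"))
    }
  }

  list(cv = cvf, aggregate = agg, normalized = norm, de = de,
       clustermap = cm, sample_dendrogram = dendro, enrichment = enr,
       network = net, angioscore = angio)
}
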