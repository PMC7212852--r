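#' Simulation configuration
#'
#' Describes the synthetic dual-species study: two conditions (core `A`,
#' invasive rim `I`) x 3 biological samples x 3 technical replicates, a
#' human and a mouse compartment, log-normal abundances with a biological
#' sample effect shared between conditions (both regions are dissected from
#' the same brain), per-protein technical noise with a heavy-tailed CV
#' mixture, and logistic low-abundance dropout.
#'
#' Abundances are generated on the log2 scale as
#' `base + sample_effect + [condition == I] * log2fc` plus technical noise
#' whose log-normal sd is chosen so the natural-scale CV equals the
#' protein's technical CV.
#'
#' @param n_human,n_mouse protein counts per compartment.
#' @param de_fraction fraction of proteins with a planted condition effect.
#' @param log2fc_range range of planted |log2FC|; signs are random.
#' @param bulk_cv technical CV of well-behaved proteins.
#' @param tail_fraction fraction of proteins drawn from the high-CV tail.
#' @param tail_cv technical CV of tail proteins (past the 0.8 gate).
#' @param sample_sd sd (log2) of the per-(protein, sample) biological effect.
#' @param base_mean,base_sd log2-abundance distribution of protein baselines.
#' @param dropout_midpoint log2 abundance at which a cell is missing with
#'   probability 1/2; `-Inf` disables dropout.
#' @param dropout_steepness slope of the logistic dropout curve.
#' @param samples,replicates design grid per condition.
#' @param seed RNG seed.
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(n_human = 750L, n_mouse = 520L,
                       de_fraction = 0.2,
                       log2fc_range = c(1, 6),
                       bulk_cv = 0.2,
                       tail_fraction = 0.2,
                       tail_cv = 1.2,
                       sample_sd = 0.5,
                       base_mean = 20, base_sd = 2,
                       dropout_midpoint = 16,
                       dropout_steepness = 1,
                       samples = 3L, replicates = 3L,
                       seed = 1L) {
  stopifnot(n_human >= 0, n_mouse >= 0, n_human + n_mouse > 0,
            de_fraction >= 0, de_fraction <= 1,
            tail_fraction >= 0, tail_fraction <= 1,
            bulk_cv > 0, tail_cv > 0,
            length(log2fc_range) == 2L, log2fc_range[1] <= log2fc_range[2],
            samples >= 1L, replicates >= 2L)
  structure(list(n_human = as.integer(n_human), n_mouse = as.integer(n_mouse),
                 de_fraction = de_fraction, log2fc_range = log2fc_range,
                 bulk_cv = bulk_cv, tail_fraction = tail_fraction,
                 tail_cv = tail_cv, sample_sd = sample_sd,
                 base_mean = base_mean, base_sd = base_sd,
                 dropout_midpoint = dropout_midpoint,
                 dropout_steepness = dropout_steepness,
                 samples = as.integer(samples),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal sd (natural log) giving a target natural-scale CV
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a dual-species quantification table with planted ground truth
#'
#' @param config a [sim_config()].
#' @return list with `table` (a `quant_table`) and `truth` (a data frame
#'   with per-protein species, baseline, planted log2FC, technical CVs and
#'   the DE flag).
#' @export
simulate_quant <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_human + config$n_mouse
  species <- rep(c("human", "mouse"), c(config$n_human, config$n_mouse))
  pre <- ifelse(species == "human", "HUM", "MUS")
  protein_id <- sprintf("%s%04d", pre, unlist(lapply(
    c(config$n_human, config$n_mouse), seq_len)))
  gene_symbol <- sub("HUM", "HGENE", sub("MUS", "MGENE", protein_id))

  is_de <- rep(FALSE, n)
  for (sp in unique(species)) {
    idx <- which(species == sp)
    k <- round(length(idx) * config$de_fraction)
    if (k > 0) is_de[sample(idx, k)] <- TRUE
  }
  fc_mag <- stats::runif(n, config$log2fc_range[1], config$log2fc_range[2])
  true_log2fc <- ifelse(is_de, fc_mag * sample(c(-1, 1), n, replace = TRUE), 0)

  is_tail <- stats::runif(n) < config$tail_fraction
  cv <- ifelse(is_tail, config$tail_cv, config$bulk_cv)
  base <- stats::rnorm(n, config$base_mean, config$base_sd)

  conds <- c("A", "I")
  cols <- expand.grid(replicate = seq_len(config$replicates),
                      sample = seq_len(config$samples),
                      condition = conds, stringsAsFactors = FALSE)
  cols <- cols[, c("condition", "sample", "replicate")]
  cols$label <- sprintf("%s_s%d_r%d", cols$condition, cols$sample,
                        cols$replicate)

  # biological sample effect: one draw per (protein, sample), shared by both
  # conditions, so it cancels from the condition contrast
  samp_eff <- matrix(stats::rnorm(n * config$samples, 0, config$sample_sd),
                     nrow = n)
  sdlog <- cv_to_sdlog(cv)
  vals <- matrix(NA_real_, n, nrow(cols),
                 dimnames = list(protein_id, cols$label))
  for (j in seq_len(nrow(cols))) {
    mu2 <- base + samp_eff[, cols$sample[j]] +
      (cols$condition[j] == "I") * true_log2fc
    vals[, j] <- 2^mu2 * exp(stats::rnorm(n, 0, sdlog))
  }
  if (is.finite(config$dropout_midpoint) && config$dropout_steepness > 0) {
    p_miss <- stats::plogis(config$dropout_steepness *
                              (config$dropout_midpoint - log2(vals)))
    vals[stats::runif(length(vals)) < p_miss] <- NA_real_
  }

  truth <- data.frame(protein_id = protein_id, gene_symbol = gene_symbol,
                      species = species, is_de = is_de,
                      true_log2fc = true_log2fc, base_log2 = base,
                      cv_A = cv, cv_I = cv, stringsAsFactors = FALSE)
  list(table = quant_table(vals, protein_id, gene_symbol, species,
                           cols[, c("label", "condition", "sample",
                                    "replicate")]),
       truth = truth)
}

#' Simulate a publication corpus with planted keyword rates
#'
#' Each gene receives `pubs_per_gene` synthetic abstracts; an abstract of a
#' core-linked gene contains an angiogenesis keyword with probability
#' `rate_core`, any other gene's with probability `rate_other`. The
#' `invasive_genes` list is accepted to validate that the two hit lists do
#' not overlap; its members score at the background rate.
#'
#' @param genes character vector of all gene symbols to cover.
#' @param core_genes genes linked to the vascularized core.
#' @param invasive_genes genes linked to the invasive rim.
#' @param rate_core,rate_other per-abstract keyword probabilities in [0, 1].
#' @param pubs_per_gene abstracts per gene (0 gives a "no publications" gene).
#' @param seed RNG seed.
#' @return a `publication_corpus` (see [read_corpus()]).
#' @export
simulate_corpus <- function(genes, core_genes = character(),
                            invasive_genes = character(),
                            rate_core = 0.3, rate_other = 0.2,
                            pubs_per_gene = 200L, seed = 1L) {
  if (length(intersect(core_genes, invasive_genes)))
    stop("core and invasive gene lists overlap: ",
         paste(intersect(core_genes, invasive_genes), collapse = ", "))
  stopifnot(rate_core >= 0, rate_core <= 1, rate_other >= 0, rate_other <= 1,
            pubs_per_gene >= 0)
  genes <- unique(c(genes, core_genes, invasive_genes))
  set.seed(as.integer(seed))
  filler <- c("Protein %s modulates cytoskeletal dynamics in glioma cells.",
              "We report that %s regulates mitochondrial metabolism.",
              "Expression of %s correlates with patient survival.",
              "%s participates in synaptic membrane trafficking.")
  hooks <- c("The data implicate %s in tumor angiogenesis.",
             "Knockdown of %s impaired angiogenesis in vivo.",
             "%s drives an angiogenic switch in xenografts.",
             "Loss of %s reduced neovascularization of the graft.")
  abstracts <- lapply(genes, function(g) {
    if (pubs_per_gene == 0L) return(character())
    rate <- if (g %in% core_genes) rate_core else rate_other
    hit <- stats::runif(pubs_per_gene) < rate
    body <- sprintf(sample(filler, pubs_per_gene, replace = TRUE), g)
    extra <- sprintf(sample(hooks, pubs_per_gene, replace = TRUE), g)
    ifelse(hit, paste(body, extra), body)
  })
  names(abstracts) <- genes
  publication_corpus(abstracts, default_lexicon())
}
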