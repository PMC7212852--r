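#' Publication corpus container
#'
#' @param abstracts named list (by gene symbol) of character vectors of
#'   abstract texts.
#' @param lexicon character vector of angiogenesis keywords/phrases.
#' @return an object of class `publication_corpus`.
#' @export
publication_corpus <- function(abstracts, lexicon = default_lexicon()) {
  if (is.null(names(abstracts)) || anyDuplicated(names(abstracts)))
    stop("abstracts must be a list uniquely named by gene")
  lexicon <- unique(trimws(lexicon))
  lexicon <- lexicon[nzchar(lexicon)]
  if (!length(lexicon)) stop("lexicon must be non-empty")
  structure(list(abstracts = abstracts, lexicon = lexicon),
            class = "publication_corpus")
}

#' Default angiogenesis keyword lexicon
#'
#' An editable starting lexicon; scores depend on the lexicon and on the
#' corpus snapshot, so absolute AngioScores are tied to both.
#'
#' @return character vector of keywords/phrases.
#' @export
default_lexicon <- function() {
  c("angiogenesis", "angiogenic", "neovascularization", "neovascular",
    "vasculogenesis", "tumor vasculature", "tumour vasculature",
    "vascular endothelial growth", "blood vessel formation",
    "endothelial sprouting")
}

#' Read a publication corpus directory
#'
#' One `<GENE>.txt` file per gene with abstracts separated by blank lines,
#' plus a `lexicon.txt` with one keyword per line.
#'
#' @param dir directory path.
#' @return a `publication_corpus`.
#' @export
read_corpus <- function(dir) {
  lex_path <- file.path(dir, "lexicon.txt")
  if (!file.exists(lex_path)) stop("missing lexicon.txt in ", dir)
  lexicon <- readLines(lex_path, warn = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.txt$"), "lexicon.txt")
  abstracts <- lapply(files, function(f) {
    lines <- readLines(file.path(dir, f), warn = FALSE)
    recs <- split(lines, cumsum(!nzchar(lines)))
    recs <- vapply(recs, function(r) paste(r[nzchar(r)], collapse = " "), "")
    unname(recs[nzchar(recs)])
  })
  names(abstracts) <- sub("\\.txt$", "", files)
  publication_corpus(abstracts, lexicon)
}

#' Write a publication corpus directory
#'
#' @param corpus a `publication_corpus`.
#' @param dir directory path (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(corpus$lexicon, file.path(dir, "lexicon.txt"))
  for (g in names(corpus$abstracts))
    writeLines(paste(corpus$abstracts[[g]], collapse = "\n\n"),
               file.path(dir, paste0(g, ".txt")))
  invisible(dir)
}

lexicon_regex <- function(lexicon) {
  esc <- gsub("([^[:alnum:] ])", "\\\\\\1", unique(lexicon))
  paste0("\\b(", paste(esc, collapse = "|"), ")\\b")
}

#' Score one gene's abstracts against the keyword lexicon
#'
#' An abstract matches if it contains at least one lexicon entry
#' (case-insensitive, whole-word/phrase). The AngioScore is
#' `100 * matching / total` abstracts; with zero abstracts the score is
#' undefined (`NA`) and the gene is excluded from group statistics.
#'
#' @param abstracts character vector of abstract texts.
#' @param lexicon character vector of keywords/phrases.
#' @return list with `n_publications`, `n_matching`, `angioscore`.
#' @export
score_gene <- function(abstracts, lexicon) {
  lexicon <- unique(trimws(lexicon))
  lexicon <- lexicon[nzchar(lexicon)]
  if (!length(lexicon)) stop("lexicon must be non-empty")
  n <- length(abstracts)
  if (n == 0L)
    return(list(n_publications = 0L, n_matching = 0L, angioscore = NA_real_))
  hit <- grepl(lexicon_regex(lexicon), abstracts,
               ignore.case = TRUE, perl = TRUE)
  list(n_publications = n, n_matching = sum(hit),
       angioscore = 100 * sum(hit) / n)
}

#' AngioScore of every gene in a corpus
#'
#' @param corpus a `publication_corpus`.
#' @param lexicon keyword lexicon (defaults to the corpus's own).
#' @return data frame `gene`, `n_publications`, `n_matching`, `angioscore`
#'   (percent; `NA` for genes without publications).
#' @export
angioscore <- function(corpus, lexicon = corpus$lexicon) {
  rows <- lapply(names(corpus$abstracts), function(g) {
    s <- score_gene(corpus$abstracts[[g]], lexicon)
    data.frame(gene = g, n_publications = s$n_publications,
               n_matching = s$n_matching, angioscore = s$angioscore,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank the strongest hits of one direction
#'
#' Significant proteins (BH-adjusted p below the configured threshold) of
#' the requested direction, ranked by |log2FC| descending.
#'
#' @param de a `de_result`.
#' @param direction `"core-up"` or `"invasive-up"`.
#' @param n how many genes to return.
#' @return character vector of gene symbols (may be shorter than `n`).
#' @export
top_hits <- function(de, direction = c("core-up", "invasive-up"), n = 30L) {
  direction <- match.arg(direction)
  sel <- de[de$significant & !is.na(de$direction) &
              de$direction == direction, ]
  sel <- sel[order(-abs(sel$log2fc), sel$gene_symbol), ]
  utils::head(sel$gene_symbol, n)
}

#' Compare AngioScores between the core and invasive hit lists
#'
#' Takes the top `top_n` genes of each area, averages their AngioScores
#' (genes without publications are excluded), forms the core/invasive
#' ratio, and runs a two-sample Welch t-test. Also reports the
#' top-20-by-score listing per area.
#'
#' @param scores data frame from [angioscore()].
#' @param core_hits,invasive_hits ranked gene lists (e.g. [top_hits()]).
#' @param top_n genes taken from the head of each list.
#' @return object of class `angioscore_comparison`: list with `mean_core`,
#'   `mean_invasive`, `ratio`, `t`, `df`, `p`, `n_core`, `n_invasive`,
#'   `top20_core`, `top20_invasive`, and the per-group score tables.
#' @export
compare_groups <- function(scores, core_hits, invasive_hits, top_n = 30L) {
  pick <- function(hits) {
    g <- utils::head(hits, top_n)
    s <- scores[match(g, scores$gene), ]
    s[!is.na(s$angioscore), ]
  }
  core <- pick(core_hits)
  inv <- pick(invasive_hits)
  if (nrow(core) < 2L || nrow(inv) < 2L)
    stop("need at least 2 scored genes per group for a t-test")
  tt <- welch_t_test(core$angioscore, inv$angioscore)
  top20 <- function(s) utils::head(s[order(-s$angioscore, s$gene), ], 20L)
  structure(list(mean_core = mean(core$angioscore),
                 mean_invasive = mean(inv$angioscore),
                 ratio = mean(core$angioscore) / mean(inv$angioscore),
                 t = tt$t, df = tt$df, p = tt$p,
                 n_core = nrow(core), n_invasive = nrow(inv),
                 top20_core = top20(core), top20_invasive = top20(inv),
                 scores_core = core, scores_invasive = inv),
            class = "angioscore_comparison")
}

#' @export
print.angioscore_comparison <- function(x, ...) {
  cat(sprintf("AngioScore comparison (n = %d core, %d invasive genes)\n",
              x$n_core, x$n_invasive))
  cat(sprintf("  mean core %.2f%%  mean invasive %.2f%%  ratio %.2f\n",
              x$mean_core, x$mean_invasive, x$ratio))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}
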