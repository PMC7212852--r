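#' Read a gene-set collection from GMT
#'
#' Tab-separated lines: set name, description, member symbols. Duplicate
#' member symbols within a set are deduplicated; sets without members are
#' skipped with a warning; a repeated set name is an error.
#'
#' @param path file path.
#' @return a `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene set: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- list(); desc <- character()
  for (f in fields) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("gene set ", f[1], " has no members; skipped")
      next
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- if (length(f) >= 2L) f[2] else ""
  }
  structure(list(sets = sets, description = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Over-representation analysis by hypergeometric test
#'
#' For each gene set, tests whether the query (e.g. the significant,
#' |log2FC| > 1 proteins) overlaps the set more than expected from the
#' universe (the detected proteome of the species analyzed), using the
#' hypergeometric upper tail P(X >= observed overlap). P-values are
#' BH-adjusted across all tested sets and rows with adjusted p below
#' `padj_cutoff` are flagged enriched. `ratio` is overlap / query size,
#' the dot-size quantity of enrichment dot plots.
#'
#' @param query character vector of gene symbols; symbols outside the
#'   universe are dropped (count reported via a message).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of eligible symbols.
#' @param padj_cutoff adjusted-p cutoff for the `enriched` flag.
#' @return data frame, one row per tested set, sorted by `padj` then
#'   `set_id`: `set_id`, `set_name`, `overlap_count`, `query_size`,
#'   `set_size`, `universe_size`, `ratio`, `p_value`, `padj`, `enriched`.
#' @export
ora_test <- function(query, collection, universe, padj_cutoff = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(length(dropped), " query symbol(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (!length(query)) stop("empty query after restriction to universe")
  N <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    if (!length(s)) return(NULL)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1L, length(s), N - length(s), n_query,
                       lower.tail = FALSE)
    data.frame(set_id = nm,
               set_name = if (nzchar(collection$description[[nm]]))
                 collection$description[[nm]] else nm,
               overlap_count = k, query_size = n_query,
               set_size = length(s), universe_size = N,
               ratio = k / n_query, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$padj <- bh_adjust(out$p_value)
  out$enriched <- out$padj < padj_cutoff
  out[order(out$padj, out$set_id), ]
}
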