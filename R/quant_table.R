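#' Protein quantification table
#'
#' A `quant_table` holds a proteins x replicate-columns abundance matrix
#' together with per-protein annotation (accession, gene symbol, species) and
#' per-column design metadata (condition, biological sample, technical
#' replicate). Abundances are strictly positive; missing measurements are
#' `NA`. Columns are labelled `<condition>_s<sample>_r<replicate>` with
#' condition `A` (angiogenic core) or `I` (invasive rim).
#'
#' @param values numeric matrix, proteins x columns; positive or `NA`.
#' @param protein_id character vector of unique accessions (row order).
#' @param gene_symbol character vector of gene symbols (row order).
#' @param species character vector, each `"human"` or `"mouse"` (row order).
#' @param columns data frame with columns `label`, `condition`, `sample`,
#'   `replicate` describing the value columns in order; if missing it is
#'   parsed from `colnames(values)`.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(values, protein_id, gene_symbol, species,
                        columns = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(columns)) columns <- parse_column_keys(colnames(values))
  stopifnot(nrow(values) == length(protein_id),
            length(protein_id) == length(gene_symbol),
            length(protein_id) == length(species),
            ncol(values) == nrow(columns))
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup))
    stop("duplicate protein_id: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(columns$label))
    stop("duplicate column label: ",
         paste(unique(columns$label[duplicated(columns$label)]), collapse = ", "))
  bad_sp <- setdiff(unique(species), c("human", "mouse"))
  if (length(bad_sp)) stop("unknown species tag: ", paste(bad_sp, collapse = ", "))
  if (any(values <= 0, na.rm = TRUE))
    stop("abundances must be > 0 (zeros are not a missing-value encoding)")
  rownames(values) <- protein_id
  colnames(values) <- columns$label
  structure(list(values = values,
                 protein_id = as.character(protein_id),
                 gene_symbol = as.character(gene_symbol),
                 species = as.character(species),
                 columns = columns),
            class = "quant_table")
}

#' Parse replicate-column labels
#'
#' Labels follow `<condition>_s<sample>_r<replicate>`, e.g. `A_s1_r2`.
#'
#' @param labels character vector of column labels.
#' @return data frame with `label`, `condition`, `sample`, `replicate`.
#' @export
parse_column_keys <- function(labels) {
  if (is.null(labels)) stop("value columns must be named")
  m <- regmatches(labels, regexec("^([AI])_s([0-9]+)_r([0-9]+)$", labels))
  bad <- labels[vapply(m, length, 1L) != 4L]
  if (length(bad))
    stop("malformed column header (want <A|I>_s<k>_r<k>): ",
         paste(bad, collapse = ", "))
  data.frame(label = labels,
             condition = vapply(m, `[`, "", 2L),
             sample = as.integer(vapply(m, `[`, "", 3L)),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins (%d human, %d mouse) x %d columns\n",
              nrow(x$values), sum(x$species == "human"),
              sum(x$species == "mouse"), ncol(x$values)))
  cat(sprintf("  conditions: %s | missing cells: %d (%.1f%%)\n",
              paste(sort(unique(x$columns$condition)), collapse = ", "),
              sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' Subset a quant_table by protein and/or column
#'
#' @param x a `quant_table`.
#' @param i protein index (logical, integer or accession character).
#' @param j column index (logical, integer or label character).
#' @param ... unused.
#' @return a `quant_table`.
#' @export
`[.quant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$protein_id)
  if (is.character(j)) j <- match(j, x$columns$label)
  quant_table(x$values[i, j, drop = FALSE],
              x$protein_id[i], x$gene_symbol[i], x$species[i],
              x$columns[j, , drop = FALSE])
}

#' Restrict a quant_table to one species
#'
#' @param x a `quant_table`.
#' @param species `"human"`, `"mouse"` or `"both"`.
#' @return a `quant_table`.
#' @export
filter_species <- function(x, species = c("both", "human", "mouse")) {
  species <- match.arg(species)
  if (species == "both") return(x)
  x[x$species == species, ]
}

#' Read a quantification table from TSV
#'
#' Expects a header row `protein_id`, `gene_symbol`, `species`, then one
#' column per replicate named in the `<A|I>_s<k>_r<k>` dialect. Empty cells
#' and the literal `NA` are missing; all other cells must parse as positive
#' reals.
#'
#' @param path file path.
#' @return a `quant_table`.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = c("", "NA"),
                          quote = "", comment.char = "")
  need <- c("protein_id", "gene_symbol", "species")
  if (!identical(names(df)[1:3], need))
    stop("first three columns must be: ", paste(need, collapse = ", "))
  val_cols <- names(df)[-(1:3)]
  if (anyDuplicated(val_cols))
    stop("duplicate column header: ",
         paste(unique(val_cols[duplicated(val_cols)]), collapse = ", "))
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, val_cols)))
  bad <- which(is.na(num) & !is.na(vals))
  if (length(bad))
    stop("non-numeric abundance value(s), e.g. '", vals[bad[1]], "'")
  if (any(num < 0, na.rm = TRUE)) stop("negative abundance value")
  quant_table(num, df$protein_id, df$gene_symbol, df$species)
}

#' Write a quantification table to TSV
#'
#' Byte-stable output: fixed column order, reals rendered with 6 significant
#' digits, `NA` for missing.
#'
#' @param x a `quant_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  df <- data.frame(protein_id = x$protein_id,
                   gene_symbol = x$gene_symbol,
                   species = x$species,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, optional = TRUE))
  write_table(df, path)
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, UTF-8, '.' decimal, no quoting, `NA` for missing, numeric
#' cells formatted with 6 significant digits so that two writes of the same
#' object are byte-identical.
#'
#' @param df a data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) {
      out <- sprintf("%.6g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
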