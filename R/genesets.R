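#' Read a gene-set file
#'
#' One gene identifier per line; blank lines and surrounding whitespace
#' are ignored; duplicate lines collapse to one (set semantics).
#'
#' @param path path to the file.
#' @return character vector of unique gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- unique(read_id_lines(path))
  if (!length(x)) stop("empty gene set in ", path)
  x
}

#' Write a gene set, one identifier per line
#' @param genes character vector (deduplicated on write).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}

#' Write a result table as TSV with a header row
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cell-type labels
#'
#' Two-column TSV (cell identifier, cell-type label), no header required;
#' a header row is detected when the first line's cell id reappears
#' nowhere and equals "cell" case-insensitively.
#'
#' @param path path to the file.
#' @return named character vector: labels named by cell identifier.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have 2 columns (cell, label)")
  if (nrow(df) && tolower(df[1, 1]) %in% c("cell", "cell_id", "barcode")) {
    df <- df[-1, , drop = FALSE]
  }
  if (!nrow(df)) stop("no label rows in ", path)
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup)) stop("duplicate cell identifier(s) in labels: ",
                        paste(dup, collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}

#' Write cell-type labels as two-column TSV
#' @param labels named character vector (names = cell identifiers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_labels <- function(labels, path) {
  utils::write.table(data.frame(cell = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a PPI network in STRING protein-links dialect
#' @param ppi a [ppi_network()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(ppi, path) {
  df <- data.frame(protein1 = ppi$gene1, protein2 = ppi$gene2,
                   combined_score = ppi$score)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
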