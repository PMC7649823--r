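#' Construct an expression matrix object
#'
#' A light container for a genes x cells expression matrix. Rows are genes,
#' columns are cells; values must be finite and non-negative. The `scale`
#' tag records whether values are raw TPM or log-transformed TPM, so that
#' the log step cannot be applied twice.
#'
#' @param values numeric matrix, genes in rows, cells in columns, with
#'   unique rownames (gene identifiers) and colnames (cell identifiers).
#' @param scale `"tpm"` for raw values or `"log_tpm"` for log-transformed.
#' @return an object of class `diffge_expr` with elements `values`,
#'   `genes`, `cells` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("tpm", "log_tpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  genes <- rownames(values)
  cells <- colnames(values)
  if (is.null(genes) || is.null(cells)) {
    stop("`values` must carry gene rownames and cell colnames")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(cells[duplicated(cells)])
  if (length(dup)) stop("duplicate cell identifier(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', cell '%s'",
                 genes[bad[1]], cells[bad[2]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', cell '%s'",
                 genes[bad[1]], cells[bad[2]]))
  }
  structure(
    list(values = values, genes = genes, cells = cells, scale = scale),
    class = "diffge_expr"
  )
}

#' @export
print.diffge_expr <- function(x, ...) {
  cat(sprintf("<diffge_expr> %d genes x %d cells [%s]\n",
              length(x$genes), length(x$cells), x$scale))
  invisible(x)
}

#' @export
dim.diffge_expr <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports a dense TSV (gene identifiers in the first column, cell
#' identifiers in the header row) and MatrixMarket coordinate triplets
#' with plain-text gene/cell name sidecar files.
#'
#' @param path path to the TSV file, or to the `.mtx` file for
#'   `format = "mtx_triplet"`.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param scale scale tag of the stored values, see [expression_matrix()].
#' @param genes_path,cells_path sidecar files (one identifier per line)
#'   for the MatrixMarket format; default to `genes.txt` / `barcodes.txt`
#'   next to `path`.
#' @return a [expression_matrix()] object; row/column order follows the file.
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            scale = c("tpm", "log_tpm"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    if (length(readLines(path, n = 2L, warn = FALSE)) < 2L) {
      stop("no data rows in ", path)
    }
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("no data rows in ", path)
    genes <- df[[1]]
    body <- df[, -1, drop = FALSE]
    cells <- colnames(body)
    vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(genes, cells))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric expression value at gene '%s', cell '%s'",
                   genes[bad[1]], cells[bad[2]]))
    }
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.txt")
    if (is.null(cells_path)) cells_path <- file.path(dir, "barcodes.txt")
    if (!file.exists(genes_path)) stop("gene name sidecar not found: ", genes_path)
    if (!file.exists(cells_path)) stop("cell name sidecar not found: ", cells_path)
    m <- Matrix::readMM(path)
    genes <- read_id_lines(genes_path)
    cells <- read_id_lines(cells_path)
    if (nrow(m) != length(genes)) {
      stop(sprintf("matrix has %d rows but %d gene names", nrow(m), length(genes)))
    }
    if (ncol(m) != length(cells)) {
      stop(sprintf("matrix has %d columns but %d cell names", ncol(m), length(cells)))
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  }
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix as dense TSV
#'
#' Inverse of [read_expression()] for the TSV format: gene identifiers in
#' the first column (`gene` header), cell identifiers as remaining headers.
#'
#' @param m a [expression_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "diffge_expr"))
  df <- data.frame(gene = m$genes, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_id_lines <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
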