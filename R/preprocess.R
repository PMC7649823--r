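#' Log-transform a TPM expression matrix
#'
#' Applies `log2(x + 1)` elementwise and retags the matrix as `log_tpm`.
#' Refuses to transform a matrix that is already on the log scale.
#'
#' @param m a [expression_matrix()] object with `scale == "tpm"`.
#' @return the transformed [expression_matrix()].
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "diffge_expr"))
  if (m$scale == "log_tpm") {
    stop("matrix is already log-scaled; refusing to transform twice")
  }
  expression_matrix(log2(m$values + 1), scale = "log_tpm")
}

#' Filter zero, rare and ubiquitous genes
#'
#' A gene is "expressed" in a cell iff its value is strictly greater than
#' `expressed_min`. Three filters are applied, in order: genes expressed
#' in no cell (zero filter); genes expressed in less than `v`% of cells
#' (rare filter, strict `<`); genes expressed in at least `(100 - v)`% of
#' cells (ubiquitous filter, `>=`). Fractions are exact
#' (`count / n_cells`), never rounded percentages. Gene order is
#' preserved; the cell set is unchanged.
#'
#' @param m a [expression_matrix()] object.
#' @param v rare/ubiquitous percentage parameter, `0 < v < 50`; default 10.
#' @param expressed_min expression threshold defining "expressed"; default 0.
#' @return a list with elements `matrix` (the filtered
#'   [expression_matrix()]) and `report` (a `diffge_filter_report`:
#'   counts of input/dropped genes per rule, `v`, `expressed_min`, and
#'   `kept_genes` in input order).
#' @export
filter_genes <- function(m, v = 10, expressed_min = 0) {
  stopifnot(inherits(m, "diffge_expr"))
  if (!(v > 0 && v < 50)) stop("`v` must satisfy 0 < v < 50")
  if (expressed_min < 0) stop("`expressed_min` must be >= 0")
  n_cells <- length(m$cells)
  n_expr <- rowSums(m$values > expressed_min)
  frac <- n_expr / n_cells
  is_zero <- n_expr == 0L
  is_rare <- !is_zero & frac < v / 100
  is_ubiq <- !is_zero & !is_rare & frac >= (100 - v) / 100
  keep <- !(is_zero | is_rare | is_ubiq)
  if (!any(keep)) {
    stop("all genes removed by the filters; lower `v` or `expressed_min`")
  }
  report <- structure(
    list(n_input_genes = length(m$genes),
         n_zero_dropped = sum(is_zero),
         n_rare_dropped = sum(is_rare),
         n_ubiquitous_dropped = sum(is_ubiq),
         v = v,
         expressed_min = expressed_min,
         kept_genes = m$genes[keep]),
    class = "diffge_filter_report"
  )
  out <- expression_matrix(m$values[keep, , drop = FALSE], scale = m$scale)
  list(matrix = out, report = report)
}

#' @export
print.diffge_filter_report <- function(x, ...) {
  cat(sprintf(
    "<diffge_filter_report> %d genes in: %d zero, %d rare (<%g%%), %d ubiquitous (>=%g%%) dropped; %d kept\n",
    x$n_input_genes, x$n_zero_dropped, x$n_rare_dropped, x$v,
    x$n_ubiquitous_dropped, 100 - x$v, length(x$kept_genes)))
  invisible(x)
}

#' Serialize a filter report as a one-row TSV
#' @param report a `diffge_filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_table(data.frame(
    n_input_genes = report$n_input_genes,
    n_zero_dropped = report$n_zero_dropped,
    n_rare_dropped = report$n_rare_dropped,
    n_ubiquitous_dropped = report$n_ubiquitous_dropped,
    n_kept = length(report$kept_genes),
    v = report$v,
    expressed_min = report$expressed_min), path)
}
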