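#' Run the full scoring pipeline in memory
#'
#' Filter -> cluster -> PPI match -> activities -> entropy -> selection.
#' Raw TPM input is log-transformed first; log-scaled input is used as
#' is. Requires at least 1 percent of the expression genes to appear in
#' the PPI node set (a smaller overlap almost always means the two
#' inputs use different identifier namespaces).
#'
#' @param expr a [expression_matrix()] object.
#' @param ppi a [ppi_network()] object, gene-level identifiers.
#' @param labels optional named character vector cell -> cell-type label.
#' @param v rare/ubiquitous filter percentage (default 10).
#' @param expressed_min expression threshold defining "expressed".
#' @param K number of gene clusters; default `max(2, round(n/100))`
#'   filtered genes per the top-fraction granularity.
#' @param seed seed for the EM initialization.
#' @param entropy_mode `"per_cell"` (literal normalization across
#'   clusters within a cell) or `"per_cluster"` (proper distribution
#'   across samples); see [compute_entropy()].
#' @param top_fraction fraction of clusters reported as differential.
#' @param aggregate score cell types (mean expression per label) instead
#'   of single cells.
#' @param max_iter,tol EM controls, see [cluster_genes()].
#' @param count_both_directions see [cluster_activity()].
#' @param verbose log stage progress to stderr.
#' @return an object of class `diffge_result`: `entropy` (table with
#'   `cluster`, `n_genes`, `n_edges`, `total_activity`, `entropy`,
#'   `rank`, `selected`), `genes` (from [differential_genes()]),
#'   `filter_report`, `clustering`, `subnetworks`, `scores`
#'   (the full `diffge_entropy` object), and `params`.
#' @export
diffge_run <- function(expr, ppi, labels = NULL, v = 10, expressed_min = 0,
                       K = NULL, seed = 1L,
                       entropy_mode = c("per_cell", "per_cluster"),
                       top_fraction = 0.1, aggregate = FALSE,
                       max_iter = 300L, tol = 1e-4,
                       count_both_directions = FALSE, verbose = FALSE) {
  entropy_mode <- match.arg(entropy_mode)
  stopifnot(inherits(expr, "diffge_expr"), inherits(ppi, "diffge_ppi"))
  say <- function(...) if (verbose) message("[diffge] ", sprintf(...))
  overlap <- mean(expr$genes %in% ppi_genes(ppi))
  if (overlap < 0.01) {
    stop(sprintf(paste0(
      "only %.2f%% of expression genes appear in the PPI network; ",
      "the two inputs likely use different identifier namespaces"),
      100 * overlap))
  }
  if (expr$scale == "tpm") {
    say("log-transforming TPM input")
    expr <- log_transform(expr)
  }
  flt <- filter_genes(expr, v = v, expressed_min = expressed_min)
  say("filters: %d -> %d genes", flt$report$n_input_genes,
      length(flt$report$kept_genes))
  n <- length(flt$report$kept_genes)
  if (is.null(K)) K <- max(2L, as.integer(round(n / 100)))
  clustering <- cluster_genes(flt$matrix, K = K, seed = seed,
                              max_iter = max_iter, tol = tol)
  say("clustered %d genes into %d clusters (requested %d)",
      n, clustering$K, K)
  subs <- match_clusters(clustering, ppi)
  frame <- build_sample_frame(flt$matrix, labels = labels,
                              aggregate = aggregate)
  W <- activity_matrix(subs, frame, count_both_directions)
  scores <- compute_entropy(W, mode = entropy_mode)
  scores <- select_top(scores, fraction = top_fraction)
  say("selected cluster(s): %s", paste(scores$selected, collapse = ", "))
  genes <- differential_genes(clustering, scores)
  tab <- scores$table
  tab <- data.frame(cluster = tab$cluster,
                    n_genes = vapply(subs, function(s) s$n_k, 0L),
                    n_edges = vapply(subs, function(s) nrow(s$edges), 0L),
                    total_activity = tab$total_activity,
                    entropy = tab$entropy,
                    rank = tab$rank,
                    selected = tab$selected)
  structure(
    list(entropy = tab, genes = genes, filter_report = flt$report,
         clustering = clustering, subnetworks = subs, scores = scores,
         params = list(v = v, expressed_min = expressed_min, K = K,
                       seed = seed, entropy_mode = entropy_mode,
                       top_fraction = top_fraction, aggregate = aggregate,
                       max_iter = max_iter, tol = tol,
                       count_both_directions = count_both_directions)),
    class = "diffge_result")
}

#' @export
print.diffge_result <- function(x, ...) {
  cat(sprintf("<diffge_result> %d clusters, %d differential genes detected\n",
              nrow(x$entropy), sum(x$genes$detected)))
  print(x$entropy, row.names = FALSE)
  invisible(x)
}

#' File-based pipeline configuration
#'
#' Gathers input/output paths and every pipeline knob with its default;
#' the configuration is serialized next to the outputs for provenance.
#'
#' @param expr_path expression matrix path.
#' @param ppi_path STRING-dialect links file path.
#' @param out_dir output directory.
#' @param format,scale expression input options, see [read_expression()].
#' @param alias_path,labels_path optional alias / cell-label files.
#' @param min_score PPI confidence threshold (default 400).
#' @inheritParams diffge_run
#' @return a `diffge_config` list.
#' @export
diffge_config <- function(expr_path, ppi_path, out_dir,
                          format = "tsv", scale = "log_tpm",
                          alias_path = NULL, labels_path = NULL,
                          min_score = 400, v = 10, expressed_min = 0,
                          K = NULL, seed = 1L, entropy_mode = "per_cell",
                          top_fraction = 0.1, aggregate = FALSE,
                          max_iter = 300L, tol = 1e-4, verbose = FALSE) {
  structure(list(expr_path = expr_path, ppi_path = ppi_path,
                 out_dir = out_dir, format = format, scale = scale,
                 alias_path = alias_path, labels_path = labels_path,
                 min_score = min_score, v = v,
                 expressed_min = expressed_min, K = K, seed = seed,
                 entropy_mode = entropy_mode, top_fraction = top_fraction,
                 aggregate = aggregate, max_iter = max_iter, tol = tol,
                 verbose = verbose),
            class = "diffge_config")
}

#' Run the pipeline from files, writing all artifacts
#'
#' Reads the inputs named in the configuration, calls [diffge_run()],
#' and writes `cluster_entropy.tsv`, `differential_genes.tsv`,
#' `filter_report.tsv`, `detected_genes.txt` and `config.tsv` into the
#' output directory. Deterministic for a fixed configuration.
#'
#' @param config a [diffge_config()].
#' @return the [diffge_run()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "diffge_config"))
  expr <- read_expression(config$expr_path, format = config$format,
                          scale = config$scale)
  ppi <- read_ppi(config$ppi_path, alias_path = config$alias_path,
                  min_score = config$min_score)
  labels <- if (!is.null(config$labels_path)) {
    read_cell_labels(config$labels_path)
  }
  res <- diffge_run(expr, ppi, labels = labels, v = config$v,
                    expressed_min = config$expressed_min, K = config$K,
                    seed = config$seed, entropy_mode = config$entropy_mode,
                    top_fraction = config$top_fraction,
                    aggregate = config$aggregate,
                    max_iter = config$max_iter, tol = config$tol,
                    verbose = config$verbose)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(res$entropy, file.path(config$out_dir, "cluster_entropy.tsv"))
  write_table(res$genes, file.path(config$out_dir, "differential_genes.tsv"))
  write_filter_report(res$filter_report,
                      file.path(config$out_dir, "filter_report.tsv"))
  write_gene_set(detected_genes(res$genes),
                 file.path(config$out_dir, "detected_genes.txt"))
  cfg <- config[!vapply(config, is.null, TRUE)]
  write_table(data.frame(key = names(cfg),
                         value = vapply(cfg, as.character, "")),
              file.path(config$out_dir, "config.tsv"))
  invisible(res)
}
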