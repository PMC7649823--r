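#' Precision and recall of a subset detection against the full-data detection
#'
#' `precision = |full ∩ subset| / |subset|`,
#' `recall = |full ∩ subset| / |full|`. When the subset detection is
#' empty the precision is missing (`NA`) and the recall is 0.
#'
#' @param de_full character vector: differential genes detected on the
#'   complete data (the gold standard); must be non-empty.
#' @param de_subset character vector: differential genes detected on a
#'   cell subset.
#' @return list with elements `precision` (may be `NA`) and `recall`.
#' @export
precision_recall <- function(de_full, de_subset) {
  de_full <- unique(as.character(de_full))
  de_subset <- unique(as.character(de_subset))
  if (!length(de_full)) stop("`de_full` is empty: recall undefined")
  inter <- length(intersect(de_full, de_subset))
  precision <- if (length(de_subset)) inter / length(de_subset) else NA_real_
  list(precision = precision, recall = inter / length(de_full))
}

#' ROC curve and AUC of a gene ranking against a truth set
#'
#' Sweeps thresholds over the distinct score values in descending order;
#' genes with equal scores enter at the same threshold step, so ties
#' produce a single diagonal ROC segment. The AUC is the trapezoidal
#' area, which equals the normalized Mann-Whitney U statistic with ties
#' counted one half.
#'
#' @param scores named numeric vector: per-gene score, larger = more
#'   differential.
#' @param truth character vector of true differential genes.
#' @param universe gene universe to evaluate within; defaults to
#'   `names(scores)`. Both `truth ∩ universe` and `universe \ truth`
#'   must be non-empty.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth, universe = names(scores)) {
  if (is.null(names(scores))) stop("`scores` must be a named vector")
  universe <- unique(as.character(universe))
  missing <- setdiff(universe, names(scores))
  if (length(missing)) {
    stop("universe gene(s) without a score: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  s <- scores[universe]
  pos <- universe %in% truth
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L) stop("no truth genes in the universe")
  if (n_neg == 0L) stop("no non-truth genes in the universe")
  if (length(unique(s)) == 1L) {
    warning("all genes share one score; AUC is 0.5 by convention")
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  steps <- !duplicated(s)                       # first index of each tie group
  grp_end <- c(which(steps)[-1] - 1L, length(s))  # last index of each group
  tp <- cumsum(pos)[grp_end]
  fp <- cumsum(!pos)[grp_end]
  points <- data.frame(threshold = c(Inf, s[steps]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) *
             (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Subsampling stability protocol
#'
#' Runs the full pipeline on all cells to obtain the gold-standard
#' detection `DE_full`, then for every fraction and repeat draws a seeded
#' random cell subset (without replacement; stratified by cell-type label
#' when labels are given, so small subsets keep every type), reruns the
#' pipeline, and records the number of detected genes, precision and
#' recall against `DE_full`. Failed repeats are recorded and skipped in
#' the summaries; missing precisions (empty detections) are excluded from
#' the per-fraction means and counted.
#'
#' @param expr a [expression_matrix()] object (all cells).
#' @param ppi a [ppi_network()] object.
#' @param labels optional named character vector cell -> cell-type label.
#' @param fractions percentages of cells to subsample (default
#'   `c(10, 30, 50, 70, 90)`).
#' @param repeats random subsets per fraction (default 10).
#' @param seed master seed; subset draws are seeded per (fraction,
#'   repeat), the pipeline always runs with its own fixed seed from
#'   `params`, so runs are reproducible end to end.
#' @param params named list of [diffge_run()] arguments applied to every
#'   pipeline run (e.g. `K`, `entropy_mode`, `top_fraction`, `v`).
#' @param stratify stratify subset draws by label (default TRUE when
#'   labels are given).
#' @return an object of class `diffge_eval`: `runs` (one row per
#'   fraction x repeat), `summary` (per-fraction means and missing/failed
#'   counts), `de_full`, `seed`.
#' @export
subset_experiment <- function(expr, ppi, labels = NULL,
                              fractions = c(10, 30, 50, 70, 90),
                              repeats = 10, seed = 1L,
                              params = list(), stratify = !is.null(labels)) {
  stopifnot(inherits(expr, "diffge_expr"), inherits(ppi, "diffge_ppi"))
  if (any(fractions <= 0 | fractions > 100)) {
    stop("`fractions` must be percentages in (0, 100]")
  }
  n_cells <- length(expr$cells)
  if (min(fractions) / 100 * n_cells < 2) {
    stop("smallest fraction yields fewer than 2 cells")
  }
  run1 <- function(m, lab) do.call(diffge_run,
                                   c(list(expr = m, ppi = ppi, labels = lab), params))
  full <- run1(expr, labels)
  de_full <- detected_genes(full$genes)
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_take <- max(2L, round(f / 100 * n_cells))
    for (ri in seq_len(repeats)) {
      sub_seed <- seed + 7919L * fi + ri
      cells <- withr::with_seed(sub_seed,
        draw_cells(expr$cells, n_take, labels, stratify))
      m_sub <- expression_matrix(expr$values[, cells, drop = FALSE],
                                 scale = expr$scale)
      res <- tryCatch(run1(m_sub, labels), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = f, repeat_ = ri, n_detected = NA_integer_,
          precision = NA_real_, recall = NA_real_, failed = TRUE)
        next
      }
      de_sub <- detected_genes(res$genes)
      pr <- precision_recall(de_full, de_sub)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, repeat_ = ri, n_detected = length(de_sub),
        precision = pr$precision, recall = pr$recall, failed = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  ok <- !runs$failed
  summary <- do.call(rbind, lapply(sort(unique(runs$fraction)), function(f) {
    r <- runs[runs$fraction == f & ok, , drop = FALSE]
    data.frame(fraction = f,
               n_runs = sum(runs$fraction == f),
               n_failed = sum(runs$fraction == f) - nrow(r),
               n_missing_precision = sum(is.na(r$precision)),
               mean_n_detected = mean(r$n_detected),
               mean_precision = mean(r$precision, na.rm = TRUE),
               mean_recall = mean(r$recall))
  }))
  structure(list(runs = runs, summary = summary, de_full = de_full,
                 seed = as.integer(seed)),
            class = "diffge_eval")
}

#' @export
print.diffge_eval <- function(x, ...) {
  cat(sprintf("<diffge_eval> |DE_full| = %d, %d runs\n",
              length(x$de_full), nrow(x$runs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

draw_cells <- function(cells, n_take, labels, stratify) {
  if (!stratify || is.null(labels)) {
    return(sample(cells, n_take))
  }
  lab <- labels[cells]
  types <- unique(unname(lab))
  # proportional allocation, at least one cell per type when possible
  n_type <- vapply(types, function(t) sum(lab == t), 0L)
  take <- stats::setNames(pmax(1, round(n_take * n_type / length(cells))),
                          types)
  picked <- unlist(lapply(types, function(t) {
    pool <- cells[lab == t]
    sample(pool, min(length(pool), take[[t]]))
  }), use.names = FALSE)
  # trim or top up to the exact subset size
  if (length(picked) > n_take) picked <- sample(picked, n_take)
  if (length(picked) < n_take) {
    extra <- sample(setdiff(cells, picked), n_take - length(picked))
    picked <- c(picked, extra)
  }
  picked
}
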