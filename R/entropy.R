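#' Build the normalized per-sample expression frame
#'
#' Samples are single cells, or cell types when `aggregate = TRUE` (each
#' type's expression vector is the mean over its cells before
#' normalization). Every sample's vector is divided by its sum, so
#' values lie in \[0, 1\] and sum to 1 per sample; an all-zero sample is
#' left as zeros with a warning. These normalized values are the edge
#' weights' ingredients: the weight of a PPI edge (i, j) in sample s is
#' the product of the two normalized expression values, read as the
#' probability that the two proteins interact in that sample.
#'
#' @param m a [expression_matrix()] object.
#' @param labels named character vector cell -> cell-type label; required
#'   when `aggregate = TRUE`, must cover all cells of `m`.
#' @param aggregate aggregate cells into cell-type samples first.
#' @return an object of class `diffge_frame`: `values` (genes x samples,
#'   column-normalized), `samples`, `aggregated`.
#' @export
build_sample_frame <- function(m, labels = NULL, aggregate = FALSE) {
  stopifnot(inherits(m, "diffge_expr"))
  V <- m$values
  if (aggregate) {
    if (is.null(labels)) stop("`labels` required when aggregating by cell type")
    missing <- setdiff(m$cells, names(labels))
    if (length(missing)) {
      stop("cells without a label: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    lab <- labels[m$cells]
    types <- unique(unname(lab))
    V <- vapply(types, function(t) {
      rowMeans(V[, lab == t, drop = FALSE])
    }, numeric(nrow(V)))
    colnames(V) <- types
  }
  cs <- colSums(V)
  if (any(cs == 0)) {
    warning(sum(cs == 0), " all-zero sample(s) left unnormalized")
  }
  scale <- ifelse(cs > 0, cs, 1)
  W <- sweep(V, 2L, scale, "/")
  structure(list(values = W, samples = colnames(W), aggregated = aggregate),
            class = "diffge_frame")
}

#' @export
print.diffge_frame <- function(x, ...) {
  cat(sprintf("<diffge_frame> %d genes x %d %s\n", nrow(x$values),
              length(x$samples), if (x$aggregated) "cell types" else "cells"))
  invisible(x)
}

#' Edge weight from two normalized expression values
#'
#' The interaction probability assigned to a PPI edge in one sample:
#' the product of the normalized expression of its two endpoint genes.
#'
#' @param e_si,e_sj normalized expression values in \[0, 1\].
#' @return `e_si * e_sj` (vectorized, commutative).
#' @export
edge_weight <- function(e_si, e_sj) {
  e_si * e_sj
}

#' Activity of one cluster across samples
#'
#' The activity of cluster k in sample s is the sum of [edge_weight()]
#' over the cluster's matched PPI edges (each unordered edge counted
#' once), divided by the number of genes in the cluster. A cluster with
#' no matched edges has activity 0 everywhere.
#'
#' @param sub one element of a `diffge_subnetworks` list.
#' @param frame a `diffge_frame` from [build_sample_frame()].
#' @param count_both_directions count each undirected edge in both
#'   orientations (doubles all activities uniformly; provably leaves the
#'   normalized shares and entropies unchanged).
#' @return numeric vector of activities, one per sample.
#' @export
cluster_activity <- function(sub, frame, count_both_directions = FALSE) {
  stopifnot(inherits(frame, "diffge_frame"))
  S <- length(frame$samples)
  if (!nrow(sub$edges)) return(stats::setNames(numeric(S), frame$samples))
  Fi <- frame$values[sub$edges$gene1, , drop = FALSE]
  Fj <- frame$values[sub$edges$gene2, , drop = FALSE]
  w <- colSums(edge_weight(Fi, Fj)) / sub$n_k
  if (count_both_directions) w <- 2 * w
  stats::setNames(w, frame$samples)
}

#' Activity matrix of all clusters
#'
#' @param subnetworks a `diffge_subnetworks` from [match_clusters()].
#' @param frame a `diffge_frame`.
#' @inheritParams cluster_activity
#' @return numeric matrix, clusters x samples.
#' @export
activity_matrix <- function(subnetworks, frame, count_both_directions = FALSE) {
  W <- t(vapply(subnetworks,
                function(s) cluster_activity(s, frame, count_both_directions),
                numeric(length(frame$samples))))
  rownames(W) <- vapply(subnetworks, function(s) as.character(s$cluster), "")
  W
}

#' Network entropy of gene clusters
#'
#' Turns a clusters x samples activity matrix into per-cluster network
#' entropies `E_k = -sum_s P_ks ln(P_ks)` (natural log, `0 ln 0 := 0`).
#' Two normalizations of the activity shares `P_ks` are available:
#'
#' * `per_cell` (default): `P_ks = W_ks / sum_k' W_k's` -- each sample's
#'   activities are normalized across clusters, so the shares of one
#'   sample sum to 1. The entropy then aggregates, over samples, how
#'   substantial the cluster's share of total activity is; it is not
#'   bounded by `ln(S)`.
#' * `per_cluster`: `P_ks = W_ks / sum_s' W_ks'` -- each cluster's
#'   activity profile is normalized across samples, a proper probability
#'   distribution, so `0 <= E_k <= ln(S)` with equality iff uniform.
#'
#' Samples (per_cell) or clusters (per_cluster) with zero total activity
#' are excluded from the normalization with a warning; a zero-activity
#' cluster gets entropy 0.
#'
#' @param activities non-negative numeric matrix, clusters x samples.
#' @param mode `"per_cell"` or `"per_cluster"`.
#' @return an object of class `diffge_entropy`: a list with `table`
#'   (data.frame: `cluster`, `total_activity`, `entropy`), `P` (shares),
#'   `W` (activities), `mode`.
#' @export
compute_entropy <- function(activities, mode = c("per_cell", "per_cluster")) {
  mode <- match.arg(mode)
  W <- as.matrix(activities)
  if (!is.numeric(W) || any(!is.finite(W))) stop("activities must be finite numeric")
  if (any(W < 0)) stop("activities must be non-negative")
  if (nrow(W) < 1L || ncol(W) < 1L) stop("need >= 1 cluster and >= 1 sample")
  if (all(W == 0)) stop("no expressed cluster edges: all activities are zero")
  if (mode == "per_cell") {
    tot <- colSums(W)
    if (any(tot == 0)) {
      warning(sum(tot == 0),
              " sample(s) with zero total activity excluded from normalization")
    }
    P <- sweep(W, 2L, ifelse(tot > 0, tot, 1), "/")
    P[, tot == 0] <- 0
  } else {
    tot <- rowSums(W)
    if (any(tot == 0)) {
      warning(sum(tot == 0),
              " cluster(s) with zero total activity excluded from normalization")
    }
    P <- sweep(W, 1L, ifelse(tot > 0, tot, 1), "/")
    P[tot == 0, ] <- 0
  }
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  E <- -rowSums(plogp)
  tab <- data.frame(cluster = seq_len(nrow(W)),
                    total_activity = rowSums(W),
                    entropy = unname(E))
  structure(list(table = tab, P = P, W = W, mode = mode),
            class = "diffge_entropy")
}

#' @export
print.diffge_entropy <- function(x, ...) {
  cat(sprintf("<diffge_entropy> %d clusters x %d samples, mode %s\n",
              nrow(x$W), ncol(x$W), x$mode))
  print(x$table)
  invisible(x)
}

#' Select the top entropy fraction of clusters
#'
#' Sorts clusters by entropy, descending, and flags the first
#' `ceiling(fraction * K)` (never fewer than one). Ties on entropy are
#' broken by larger total activity, then by lower cluster index.
#'
#' @param entropy a `diffge_entropy` from [compute_entropy()].
#' @param fraction fraction of clusters to select, `0 < fraction <= 1`
#'   (default 0.1, the top 10 percent).
#' @return the `diffge_entropy` with `rank` and `selected` columns added
#'   to its table (rank 1 = highest entropy) and a `selected` element
#'   (the selected cluster indices, by rank).
#' @export
select_top <- function(entropy, fraction = 0.1) {
  stopifnot(inherits(entropy, "diffge_entropy"))
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  tab <- entropy$table
  K <- nrow(tab)
  ord <- order(-tab$entropy, -tab$total_activity, tab$cluster)
  rank <- integer(K)
  rank[ord] <- seq_len(K)
  n_sel <- min(K, max(1L, as.integer(ceiling(fraction * K))))
  tab$rank <- rank
  tab$selected <- rank <= n_sel
  entropy$table <- tab
  entropy$selected <- tab$cluster[ord][seq_len(n_sel)]
  entropy
}

#' Differential gene table from selected clusters
#'
#' Every filtered gene inherits its cluster's entropy as score; genes of
#' selected clusters form the detected differential set.
#'
#' @param clustering a `diffge_clustering`.
#' @param entropy a `diffge_entropy` after [select_top()].
#' @return data.frame with columns `gene`, `cluster`, `score`, `detected`.
#' @export
differential_genes <- function(clustering, entropy) {
  stopifnot(inherits(clustering, "diffge_clustering"),
            inherits(entropy, "diffge_entropy"))
  if (is.null(entropy$selected) || !length(entropy$selected)) {
    stop("no clusters selected; run select_top() first")
  }
  cl <- unname(clustering$assignments)
  data.frame(gene = names(clustering$assignments),
             cluster = cl,
             score = entropy$table$entropy[cl],
             detected = cl %in% entropy$selected,
             stringsAsFactors = FALSE)
}

#' Detected gene set from a differential gene table
#' @param genes data.frame from [differential_genes()].
#' @return character vector of detected gene identifiers.
#' @export
detected_genes <- function(genes) {
  genes$gene[genes$detected]
}
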