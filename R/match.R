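#' Intersect gene clusters with the PPI network
#'
#' For every cluster, records the PPI edges whose two endpoints both
#' belong to the cluster. Edges crossing cluster boundaries are discarded
#' (the cluster activity sums only over within-cluster pairs). Genes
#' absent from the PPI node set remain cluster members with no incident
#' matched edges; an empty intersection is a valid outcome.
#'
#' @param clustering a `diffge_clustering` from [cluster_genes()].
#' @param ppi a [ppi_network()] object.
#' @return an object of class `diffge_subnetworks`: a list with one
#'   element per cluster (in cluster-index order), each a list with
#'   `cluster`, `genes`, `edges` (data.frame `gene1`, `gene2`, `score`;
#'   each unordered edge once), and `n_k`.
#' @export
match_clusters <- function(clustering, ppi) {
  stopifnot(inherits(clustering, "diffge_clustering"),
            inherits(ppi, "diffge_ppi"))
  cl_of <- clustering$assignments
  c1 <- cl_of[ppi$gene1]
  c2 <- cl_of[ppi$gene2]
  within <- !is.na(c1) & !is.na(c2) & c1 == c2
  subs <- lapply(seq_len(clustering$K), function(k) {
    genes <- cluster_members(clustering, k)
    edges <- as.data.frame(ppi)[within & !is.na(c1) & c1 == k, , drop = FALSE]
    rownames(edges) <- NULL
    list(cluster = k, genes = genes, edges = edges, n_k = length(genes))
  })
  structure(subs, class = "diffge_subnetworks")
}

#' @export
print.diffge_subnetworks <- function(x, ...) {
  cat(sprintf("<diffge_subnetworks> %d clusters; edges per cluster: %s\n",
              length(x), paste(vapply(x, function(s) nrow(s$edges), 0L),
                               collapse = ", ")))
  invisible(x)
}

#' Write per-cluster matched edge lists as one TSV
#' @param subnetworks a `diffge_subnetworks`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subnetworks <- function(subnetworks, path) {
  rows <- do.call(rbind, lapply(subnetworks, function(s) {
    if (!nrow(s$edges)) return(NULL)
    data.frame(cluster = s$cluster, s$edges)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster = integer(), gene1 = character(),
                       gene2 = character(), score = numeric())
  }
  write_table(rows, path)
}
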