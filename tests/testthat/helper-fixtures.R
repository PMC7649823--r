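# in-code fixtures and independent oracles shared across test files

make_expr <- function(values, genes = NULL, cells = NULL,
                      scale = "log_tpm") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, scale = scale)
}

# hand-built clustering object bypassing the EM, for testing downstream stages
make_clustering <- function(assignments) {
  cl <- as.integer(assignments)
  structure(
    list(assignments = stats::setNames(cl, names(assignments)),
         K = max(cl), K_requested = max(cl),
         sizes = tabulate(cl, nbins = max(cl)),
         seed = 0L, converged = TRUE, n_iter = 0L, loglik = NA_real_),
    class = "diffge_clustering")
}

make_frame <- function(values) {
  structure(list(values = values, samples = colnames(values),
                 aggregated = FALSE),
            class = "diffge_frame")
}

# independent entropy oracle: plain double loops over the definitions
brute_entropy <- function(W, mode) {
  K <- nrow(W); S <- ncol(W)
  P <- matrix(0, K, S)
  if (mode == "per_cell") {
    for (s in seq_len(S)) {
      tot <- 0
      for (k in seq_len(K)) tot <- tot + W[k, s]
      if (tot > 0) for (k in seq_len(K)) P[k, s] <- W[k, s] / tot
    }
  } else {
    for (k in seq_len(K)) {
      tot <- 0
      for (s in seq_len(S)) tot <- tot + W[k, s]
      if (tot > 0) for (s in seq_len(S)) P[k, s] <- W[k, s] / tot
    }
  }
  E <- numeric(K)
  for (k in seq_len(K)) {
    for (s in seq_len(S)) {
      if (P[k, s] > 0) E[k] <- E[k] - P[k, s] * log(P[k, s])
    }
  }
  E
}

# independent AUC oracle: exhaustive Mann-Whitney pair counting, ties = 1/2
mw_auc <- function(scores, truth) {
  pos <- scores[names(scores) %in% truth]
  neg <- scores[!(names(scores) %in% truth)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# cluster containing most of a planted gene block (plurality overlap)
block_cluster <- function(clustering, block_genes) {
  cl <- clustering$assignments[names(clustering$assignments) %in% block_genes]
  as.integer(names(which.max(table(cl))))
}
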