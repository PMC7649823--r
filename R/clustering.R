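#' Partition genes by EM mixture clustering
#'
#' Fits a Gaussian mixture with diagonal covariances to the gene
#' expression profiles (genes as observations, cells as features) by
#' expectation-maximization and returns hard cluster assignments by
#' maximum posterior responsibility. Initialization is k-means++ style
#' from the given seed, so runs are fully reproducible. Clusters left
#' empty after hard assignment are removed and the remaining indices
#' compacted, so the effective number of clusters can be smaller than
#' requested (recorded in the result).
#'
#' @param m a log-scaled [expression_matrix()] of the filtered genes.
#' @param K requested number of clusters, `2 <= K <= n_genes`.
#' @param seed integer seed driving initialization.
#' @param max_iter maximum EM iterations (default 300).
#' @param tol convergence tolerance on the change in log-likelihood per
#'   observation (default 1e-4).
#' @param var_floor lower bound on per-feature variances, guards
#'   degenerate components.
#' @param n_init number of initializations (k-means++ draw refined by a
#'   short k-means run, then a full EM fit each); the fit with the best
#'   final log-likelihood is kept.
#' @return an object of class `diffge_clustering`: `assignments` (named
#'   integer vector gene -> cluster in `1..K_eff`), `K` (effective),
#'   `K_requested`, `sizes`, `seed`, `converged`, `n_iter`, `loglik`.
#' @export
cluster_genes <- function(m, K, seed = 1L, max_iter = 300L, tol = 1e-4,
                          var_floor = 1e-6, n_init = 5L) {
  stopifnot(inherits(m, "diffge_expr"))
  if (m$scale != "log_tpm") stop("clustering expects log-scaled expression")
  X <- m$values
  n <- nrow(X)
  if (K < 2) stop("`K` must be >= 2")
  if (K > n) stop(sprintf("`K` (%d) exceeds the number of genes (%d)", K, n))
  inits <- withr::with_seed(seed, lapply(seq_len(max(1L, n_init)),
                                         function(i) init_centers(X, K)))
  fits <- lapply(inits, function(cen) {
    em_diag_gmm(X, cen, max_iter = max_iter, tol = tol,
                var_floor = var_floor)
  })
  fit <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]
  if (!fit$converged) {
    warning(sprintf("EM did not converge within %d iterations", max_iter))
  }
  # hard assignment: argmax responsibility, ties -> lowest cluster index
  lab <- apply(fit$resp, 1L, which.max)
  # compact empty clusters
  used <- sort(unique(lab))
  lab <- match(lab, used)
  sizes <- tabulate(lab, nbins = length(used))
  structure(
    list(assignments = stats::setNames(as.integer(lab), m$genes),
         K = length(used),
         K_requested = as.integer(K),
         sizes = sizes,
         seed = as.integer(seed),
         converged = fit$converged,
         n_iter = fit$n_iter,
         loglik = fit$loglik),
    class = "diffge_clustering"
  )
}

#' @export
print.diffge_clustering <- function(x, ...) {
  cat(sprintf("<diffge_clustering> %d genes in %d clusters (requested %d), %s after %d iterations\n",
              length(x$assignments), x$K, x$K_requested,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Genes of one cluster
#' @param clustering a `diffge_clustering`.
#' @param k cluster index.
#' @return character vector of gene identifiers.
#' @export
cluster_members <- function(clustering, k) {
  names(clustering$assignments)[clustering$assignments == k]
}

#' Write cluster assignments as two-column TSV
#' @param clustering a `diffge_clustering`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  write_table(data.frame(gene = names(clustering$assignments),
                         cluster = unname(clustering$assignments)), path)
}

# One initialization: a k-means++ draw refined by a short k-means run
# (falls back to the raw draw on degenerate inputs, e.g. duplicate
# centers). Consumes RNG; callers seed it.
init_centers <- function(X, K) {
  cen <- kmeanspp_centers(X, K)
  fit <- tryCatch(stats::kmeans(X, centers = cen, iter.max = 50L),
                  error = function(e) NULL)
  if (is.null(fit)) cen else fit$centers
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center. Consumes RNG; callers seed it.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx[1], ], "-")^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx[k] <- sample.int(n, 1L)
    } else {
      idx[k] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[k], ], "-")^2))
  }
  X[idx, , drop = FALSE]
}

# EM for a Gaussian mixture with diagonal covariances.
# X: n x d observations; centers: K x d initial means.
em_diag_gmm <- function(X, centers, max_iter, tol, var_floor) {
  n <- nrow(X); d <- ncol(X); K <- nrow(centers)
  mu <- centers
  v0 <- pmax(apply(X, 2L, stats::var), var_floor)
  if (any(!is.finite(v0))) v0 <- rep(1, d)   # single-column degenerate guard
  sig2 <- matrix(v0, K, d, byrow = TRUE)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  n_iter <- 0L
  resp <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # E-step in log space
    logd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      z <- sweep(X, 2L, mu[k, ], "-")
      logd[, k] <- log(w[k]) -
        0.5 * sum(log(2 * pi * sig2[k, ])) -
        0.5 * rowSums(sweep(z^2, 2L, sig2[k, ], "/"))
    }
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    # M-step
    Nk <- colSums(resp)
    Nk <- pmax(Nk, 1e-12)
    w <- Nk / n
    mu <- (t(resp) %*% X) / Nk
    ex2 <- (t(resp) %*% X^2) / Nk
    sig2 <- pmax(ex2 - mu^2, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) / n < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(resp = resp, mu = mu, sig2 = sig2, w = w,
       loglik = ll_old, converged = converged, n_iter = n_iter)
}
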