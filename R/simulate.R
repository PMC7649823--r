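#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 5 co-expression blocks of 40 genes over 2 cell types of 60
#' cells, one block differential with a 3 log-TPM shift (3 standard
#' deviations of the gene-level noise), 20 percent dropout, and a PPI
#' graph with 0.3 within-block and 0.01 background edge probability.
#'
#' The expression model is
#' `value = max(0, mu_block,type + burst_block,cell + noise_gene,cell)`
#' followed by dropout zeroing. `base_mean` is the background log-TPM
#' level shared by all constant blocks; `coexpr_sd` is the standard
#' deviation of a per-(block, cell) burst factor shared by all genes of a
#' block, which is what makes blocks co-expressed (correlated across
#' cells) and gives background activity its sporadic, bursty character;
#' `noise_sd` is independent gene-level noise. Differential blocks are
#' elevated by `block_mean_shift` in one cell type (assigned cyclically).
#'
#' @param n_genes total genes (must be divisible by `n_blocks`).
#' @param n_cells total cells (must be divisible by `n_cell_types`).
#' @param n_blocks co-expression blocks partitioning the genes.
#' @param n_differential_blocks blocks whose mean differs between cell
#'   types.
#' @param n_cell_types cell populations (>= 2).
#' @param block_mean_shift effect size in log-TPM units.
#' @param base_mean background mean expression, log-TPM units.
#' @param coexpr_sd sd of the shared per-block-per-cell burst factor.
#' @param noise_sd sd of independent gene-level Gaussian noise.
#' @param dropout_rate probability that a value is zeroed.
#' @param ppi_within_block_prob,ppi_background_prob PPI edge
#'   probabilities within and between blocks.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return a validated `diffge_sim_config` list.
#' @export
simulation_config <- function(n_genes = 200, n_cells = 120, n_blocks = 5,
                              n_differential_blocks = 1, n_cell_types = 2,
                              block_mean_shift = 3, base_mean = 1,
                              coexpr_sd = 1.5, noise_sd = 1,
                              dropout_rate = 0.2,
                              ppi_within_block_prob = 0.3,
                              ppi_background_prob = 0.01, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_cells = n_cells, n_blocks = n_blocks,
              n_differential_blocks = n_differential_blocks,
              n_cell_types = n_cell_types,
              block_mean_shift = block_mean_shift, base_mean = base_mean,
              coexpr_sd = coexpr_sd, noise_sd = noise_sd,
              dropout_rate = dropout_rate,
              ppi_within_block_prob = ppi_within_block_prob,
              ppi_background_prob = ppi_background_prob,
              seed = as.integer(seed))
  probs <- c(cfg$dropout_rate, cfg$ppi_within_block_prob,
             cfg$ppi_background_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_differential_blocks > cfg$n_blocks) {
    stop("`n_differential_blocks` must be <= `n_blocks`")
  }
  if (cfg$n_cell_types < 2) stop("`n_cell_types` must be >= 2")
  if (cfg$n_genes %% cfg$n_blocks != 0) {
    stop("`n_genes` must be divisible by `n_blocks`")
  }
  if (cfg$n_cells %% cfg$n_cell_types != 0) {
    stop("`n_cells` must be divisible by `n_cell_types`")
  }
  if (cfg$noise_sd < 0 || cfg$coexpr_sd < 0) stop("sds must be >= 0")
  structure(cfg, class = "diffge_sim_config")
}

#' Simulate an expression matrix, labels, PPI network and ground truth
#'
#' Draws the block-structured scRNA-seq emulation described in
#' [simulation_config()]: genes partitioned into co-expression blocks,
#' cell populations in which the differential blocks change mean
#' activity, dropout zeros, and a PPI graph enriched for within-block
#' edges (within-block edges drawn with `ppi_within_block_prob`,
#' cross-block with `ppi_background_prob`; scores uniform on 400-999).
#' Values are generated directly on the log-TPM scale, so the pipeline's
#' log step is skipped on synthetic input.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (a [expression_matrix()], scale `log_tpm`),
#'   `labels` (named character vector cell -> type), `ppi`
#'   (a [ppi_network()]), and `truth` (list: `blocks` named gene ->
#'   block index, `differential_blocks`, `active_type` per differential
#'   block, `cell_types`).
#' @export
simulate_diffge <- function(config = simulation_config()) {
  stopifnot(inherits(config, "diffge_sim_config"))
  withr::with_seed(config$seed, {
    G <- config$n_genes; S <- config$n_cells
    nb <- config$n_blocks; nt <- config$n_cell_types
    genes <- sprintf("G%04d", seq_len(G))
    cells <- sprintf("C%04d", seq_len(S))
    block <- rep(seq_len(nb), each = G / nb)
    type <- rep(seq_len(nt), each = S / nt)
    diff_blocks <- seq_len(config$n_differential_blocks)
    # cell type in which each differential block is elevated, cyclic,
    # skipping type 1 so every differential block has a reference state
    active_type <- ((diff_blocks - 1L) %% (nt - 1L)) + 2L
    mu <- matrix(config$base_mean, nb, nt)
    for (i in seq_along(diff_blocks)) {
      mu[diff_blocks[i], active_type[i]] <-
        config$base_mean + config$block_mean_shift
    }
    burst <- matrix(stats::rnorm(nb * S, 0, config$coexpr_sd), nb, S)
    noise <- matrix(stats::rnorm(G * S, 0, config$noise_sd), G, S)
    V <- pmax(0, mu[cbind(rep(block, S), rep(type, each = G))] +
                 burst[cbind(rep(block, S), rep(seq_len(S), each = G))] +
                 noise)
    V <- matrix(V, G, S, dimnames = list(genes, cells))
    if (config$dropout_rate > 0) {
      V[matrix(stats::runif(G * S) < config$dropout_rate, G, S)] <- 0
    }
    expr <- expression_matrix(V, scale = "log_tpm")
    labels <- stats::setNames(sprintf("T%d", type), cells)
    # PPI: Bernoulli per unordered gene pair, block-dependent probability
    pair <- which(upper.tri(diag(G)), arr.ind = TRUE)
    within <- block[pair[, 1]] == block[pair[, 2]]
    p <- ifelse(within, config$ppi_within_block_prob,
                config$ppi_background_prob)
    keep <- stats::runif(nrow(pair)) < p
    ppi <- ppi_network(genes[pair[keep, 1]], genes[pair[keep, 2]],
                       sample(400:999, sum(keep), replace = TRUE))
    truth <- list(blocks = stats::setNames(block, genes),
                  differential_blocks = diff_blocks,
                  active_type = stats::setNames(sprintf("T%d", active_type),
                                                as.character(diff_blocks)),
                  cell_types = sprintf("T%d", seq_len(nt)))
    list(expr = expr, labels = labels, ppi = ppi, truth = truth)
  })
}

#' Write all four simulation outputs to a directory
#'
#' Emits `expression.tsv`, `labels.tsv`, `ppi_links.txt` and
#' `truth_genes.txt` (the genes of the differential blocks) in the
#' formats the readers of this package accept.
#'
#' @param sim result of [simulate_diffge()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_cell_labels(sim$labels, file.path(dir, "labels.tsv"))
  write_ppi(sim$ppi, file.path(dir, "ppi_links.txt"))
  truth_genes <- names(sim$truth$blocks)[
    sim$truth$blocks %in% sim$truth$differential_blocks]
  write_gene_set(truth_genes, file.path(dir, "truth_genes.txt"))
  invisible(dir)
}
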