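test_that("sample frames normalize each sample to unit total", {
  m <- make_expr(matrix(c(2, 3, 5), 3, 1))
  fr <- build_sample_frame(m)
  expect_equal(unname(fr$values[, 1]), c(0.2, 0.3, 0.5))

  m2 <- make_expr(matrix(c(2, 0, 0, 2), 2, 2), cells = c("c1", "c2"))
  fr2 <- build_sample_frame(m2, labels = c(c1 = "T", c2 = "T"),
                            aggregate = TRUE)
  expect_equal(unname(fr2$values[, "T"]), c(0.5, 0.5))

  m3 <- make_expr(matrix(c(1, 1, 0, 0), 2, 2))
  expect_warning(fr3 <- build_sample_frame(m3), "all-zero")
  expect_equal(unname(fr3$values[, 2]), c(0, 0))
})

test_that("aggregation requires complete labels", {
  m <- make_expr(matrix(1, 2, 2), cells = c("c1", "c2"))
  expect_error(build_sample_frame(m, aggregate = TRUE), "labels")
  expect_error(build_sample_frame(m, labels = c(c1 = "T"), aggregate = TRUE),
               "without a label")
})

test_that("edge weights are expression products", {
  expect_equal(edge_weight(0.5, 0.4), 0.2)
  expect_equal(edge_weight(0.7, 0), 0)
  expect_equal(edge_weight(1, 1), 1)
  expect_equal(edge_weight(0.3, 0.9), edge_weight(0.9, 0.3))
})

test_that("cluster activity is the size-scaled sum over matched edges", {
  frame <- make_frame(matrix(c(0.5, 0.4, 0.1), 3, 1,
                             dimnames = list(c("A", "B", "C"), "s1")))
  sub <- list(cluster = 1L, genes = c("A", "B", "C"),
              edges = data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                                 score = c(900, 900)),
              n_k = 3L)
  expect_equal(unname(cluster_activity(sub, frame)), 0.08)
  # doubling every edge weight doubles the activity
  frame2 <- make_frame(sqrt(2) * frame$values)
  expect_equal(unname(cluster_activity(sub, frame2)), 0.16)
  # no matched edges -> zero
  sub0 <- list(cluster = 2L, genes = "A",
               edges = data.frame(gene1 = character(), gene2 = character(),
                                  score = numeric()), n_k = 1L)
  expect_equal(unname(cluster_activity(sub0, frame)), 0)
})

test_that("entropies match the hand-computed definitions in both modes", {
  # uniform activity over 4 samples: maximum entropy ln 4
  W <- rbind(rep(0.3, 4), c(0.6, 0, 0, 0))
  e <- compute_entropy(W, mode = "per_cluster")
  expect_equal(e$table$entropy[1], log(4), tolerance = 1e-12)
  expect_equal(e$table$entropy[2], 0, tolerance = 1e-12)

  e2 <- compute_entropy(rbind(c(1, 3), c(3, 1)), mode = "per_cell")
  expect_equal(unname(e2$P), rbind(c(0.25, 0.75), c(0.75, 0.25)))
  want <- -(0.25 * log(0.25) + 0.75 * log(0.75))
  expect_equal(e2$table$entropy, c(want, want), tolerance = 1e-12)
})

test_that("entropy normalization handles zeros per contract", {
  expect_error(compute_entropy(matrix(0, 2, 2)), "no expressed cluster edges")
  expect_warning(e <- compute_entropy(rbind(c(1, 0), c(1, 0)),
                                      mode = "per_cell"), "zero total")
  expect_equal(colSums(e$P), c(1, 0))
  expect_warning(e2 <- compute_entropy(rbind(c(1, 1), c(0, 0)),
                                       mode = "per_cluster"), "zero total")
  expect_equal(e2$table$entropy[2], 0)
  expect_error(compute_entropy(rbind(c(1, -1))), "non-negative")
})

test_that("shares are scale-invariant per axis and entropy is permutation-stable", {
  withr::with_seed(8, {
    W <- matrix(runif(30, 0.01, 1), 5, 6)
    cell_scale <- runif(6, 0.1, 10)
    cl_scale <- runif(5, 0.1, 10)
    perm <- sample(6)
  })
  a <- compute_entropy(W, mode = "per_cell")
  b <- compute_entropy(sweep(W, 2, cell_scale, "*"), mode = "per_cell")
  expect_equal(a$table$entropy, b$table$entropy, tolerance = 1e-12)
  a2 <- compute_entropy(W, mode = "per_cluster")
  b2 <- compute_entropy(sweep(W, 1, cl_scale, "*"), mode = "per_cluster")
  expect_equal(a2$table$entropy, b2$table$entropy, tolerance = 1e-12)
  p <- compute_entropy(W[, perm], mode = "per_cluster")
  expect_equal(p$table$entropy, a2$table$entropy, tolerance = 1e-12)
})

test_that("per-cluster entropy is bounded by ln(S), attained only at uniformity", {
  withr::with_seed(12, W <- matrix(runif(40, 0.01, 1), 5, 8))
  e <- compute_entropy(W, mode = "per_cluster")
  expect_true(all(e$table$entropy <= log(8) + 1e-9))
  expect_true(all(e$table$entropy < log(8) - 1e-9))  # random != uniform
  u <- compute_entropy(matrix(2, 1, 8), mode = "per_cluster")
  expect_equal(u$table$entropy, log(8), tolerance = 1e-9)
})

test_that("top-fraction selection uses ceil with activity/index tie-breaks", {
  mk <- function(E, act) {
    structure(list(table = data.frame(cluster = seq_along(E),
                                      total_activity = act, entropy = E),
                   P = NULL, W = NULL, mode = "per_cluster"),
              class = "diffge_entropy")
  }
  withr::with_seed(2, e30 <- mk(runif(30), runif(30)))
  expect_length(select_top(e30, 0.1)$selected, 3L)
  withr::with_seed(2, e5 <- mk(runif(5), runif(5)))
  expect_length(select_top(e5, 0.1)$selected, 1L)

  tie <- select_top(mk(c(2, 1, 2), c(0.1, 9, 0.5)), 0.34)
  expect_equal(tie$table$rank, c(2L, 3L, 1L))   # larger activity wins the tie
  expect_equal(tie$selected[1], 3L)
  # exact ties all round: lower index first
  tie2 <- select_top(mk(c(1, 1), c(2, 2)), 1)
  expect_equal(tie2$selected, c(1L, 2L))
})

test_that("differential gene tables union the selected clusters", {
  cl <- make_clustering(stats::setNames(c(1, 1, 1, 2, 2, 2, 2, 3),
                                        sprintf("g%d", 1:8)))
  e <- structure(list(table = data.frame(cluster = 1:3,
                                         total_activity = c(1, 1, 1),
                                         entropy = c(0.9, 0.7, 0.1)),
                      mode = "per_cluster"),
                 class = "diffge_entropy")
  expect_error(differential_genes(cl, e), "select_top")
  sel <- select_top(e, 0.5)
  dg <- differential_genes(cl, sel)
  expect_equal(sum(dg$detected), 7L)
  expect_setequal(detected_genes(dg), sprintf("g%d", 1:7))
  expect_equal(dg$score, c(0.9, 0.7, 0.1)[dg$cluster])
  all_sel <- differential_genes(cl, select_top(e, 1))
  expect_true(all(all_sel$detected))
})
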