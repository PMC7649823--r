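test_that("dense TSV expression matrices parse with order preserved", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "gA\t1\t0", "gB\t2\t3", "gC\t0\t0"), f)
  m <- read_expression(f, format = "tsv", scale = "tpm")
  expect_equal(m$genes, c("gA", "gB", "gC"))
  expect_equal(m$cells, c("c1", "c2"))
  expect_equal(unname(m$values), matrix(c(1, 2, 0, 0, 3, 0), 3, 2))
  expect_identical(m$scale, "tpm")
})

test_that("malformed expression input produces located hard errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tc1", f)
  expect_error(read_expression(f, scale = "tpm"), "no data rows")

  writeLines(c("gene\tc1", "GAPDH\t1", "GAPDH\t2"), f)
  expect_error(read_expression(f, scale = "tpm"), "GAPDH")

  writeLines(c("gene\tc1\tc2", "gA\t1\t-3"), f)
  expect_error(read_expression(f, scale = "tpm"), "negative.*gA.*c2")

  writeLines(c("gene\tc1\tc2", "gA\t1\tfoo"), f)
  expect_error(read_expression(f, scale = "tpm"), "non-numeric.*gA.*c2")
})

test_that("expression matrices round-trip through TSV and MTX triplet", {
  m <- make_expr(matrix(c(0.125, 2.5, 0, 3.75, 1.2345, 0.001), 3, 2),
                 scale = "tpm")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  back <- read_expression(f, format = "tsv", scale = "tpm")
  expect_equal(back$genes, m$genes)
  expect_equal(back$values, m$values, tolerance = 1e-9)

  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "m.mtx"))
  writeLines(m$genes, file.path(dir, "genes.txt"))
  writeLines(m$cells, file.path(dir, "barcodes.txt"))
  back2 <- read_expression(file.path(dir, "m.mtx"), format = "mtx_triplet",
                           scale = "tpm")
  expect_equal(back2$values, m$values, tolerance = 1e-9)
})

test_that("STRING links parsing collapses duplicates, loops and aliases", {
  dir <- withr::local_tempdir()
  links <- file.path(dir, "links.txt")
  alias <- file.path(dir, "alias.tsv")
  writeLines(c("protein1 protein2 combined_score",
               "p1 p2 900", "p2 p1 900", "p1 p1 950"), links)
  writeLines(c("p1\tA", "p2\tB"), alias)
  net <- read_ppi(links, alias, min_score = 400)
  expect_equal(nrow(net), 1L)
  expect_equal(net$gene1, "A")
  expect_equal(net$gene2, "B")
  expect_equal(net$score, 900)
})

test_that("score thresholding drops edges below min_score", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("p1 p2 150", f)
  expect_equal(nrow(read_ppi(f, min_score = 400)), 0L)

  writeLines(c("a b 900", "a c 710", "b c 650", "c d 150"), f)
  expect_equal(nrow(read_ppi(f, min_score = 700)), 2L)

  # a lone non-numeric first row reads as a header; a later one is malformed
  writeLines(c("a b 900", "b c xyz"), f)
  expect_error(read_ppi(f), "malformed score")
})

test_that("raising min_score always yields a subnetwork (idempotence in threshold)", {
  f <- withr::local_tempfile(fileext = ".txt")
  set.seed(11)
  n <- 60
  writeLines(sprintf("p%d p%d %d", sample(20, n, TRUE), sample(20, n, TRUE),
                     sample(0:999, n, TRUE)), f)
  lo <- read_ppi(f, min_score = 200)
  hi <- read_ppi(f, min_score = 650)
  key <- function(x) paste(x$gene1, x$gene2)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("alias collisions keep the first mapping with a warning", {
  dir <- withr::local_tempdir()
  links <- file.path(dir, "links.txt")
  alias <- file.path(dir, "alias.tsv")
  writeLines(c("p1 p2 800", "p1 p3 800"), links)
  writeLines(c("p1\tA", "p1\tZ", "p2\tB"), alias)
  expect_warning(net <- read_ppi(links, alias), "first mapping")
  # p3 unmapped: its edge is dropped; p1 maps to A, never Z
  expect_equal(nrow(net), 1L)
  expect_setequal(c(net$gene1, net$gene2), c("A", "B"))
})

test_that("gene sets round-trip with set semantics", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_gene_set(c("g1", "g2"), f)
  expect_setequal(read_gene_set(f), c("g1", "g2"))

  writeLines(c("g1", "g1", "", "g2", "", ""), f)
  expect_setequal(read_gene_set(f), c("g1", "g2"))

  writeLines(c("", ""), f)
  expect_error(read_gene_set(f), "empty gene set")
})

test_that("cell labels read back as a named vector", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cell_labels(c(c1 = "typeA", c2 = "typeB"), f)
  lab <- read_cell_labels(f)
  expect_equal(lab, c(c1 = "typeA", c2 = "typeB"))
})
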