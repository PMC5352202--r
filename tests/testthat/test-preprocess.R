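test_that("TSV and triplet readers reproduce the on-disk values exactly", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1\tc2", "g1\t1\t0", "g2\t2\t3"), tsv)
  E <- read_expression(tsv, "tsv")
  expect_identical(unname(E$values), matrix(c(1, 2, 0, 3), 2))
  expect_identical(E$gene_ids, c("g1", "g2"))

  # a triplet file listing a single entry densifies with explicit zeros
  mtx <- tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "2 1 5"), mtx)
  writeLines(c("g1", "g2"), paste0(mtx, ".rownames"))
  writeLines(c("c1", "c2"), paste0(mtx, ".colnames"))
  M <- read_expression(mtx, "mtx-triplet")
  expect_identical(unname(M$values), matrix(c(0, 5, 0, 0), 2))
})

test_that("malformed or inconsistent input files are rejected with context", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1\tc2", "g1\t1\t0", "g1\t2\t3"), tsv)
  expect_error(read_expression(tsv), "duplicate gene ids")
  writeLines(c("gene_id\tc1\tc1", "g1\t1\t0"), tsv)
  expect_error(read_expression(tsv), "duplicate cell ids")
  writeLines(c("gene_id\tc1", "g1\tnot_a_number"), tsv)
  expect_error(read_expression(tsv), "parse error")
  expect_error(expression_matrix(matrix(-1, 1, 1), "g1", "c1"), ">= 0")
  expect_error(expression_matrix(matrix(NaN, 1, 1), "g1", "c1"), "finite")
})

test_that("housekeeping filter retains exactly the cells expressing ACTB or GAPDH", {
  vals <- rbind(ACTB  = c(0, 0,   5, 0),
                GAPDH = c(0, 0.1, 0, 2),
                g3    = c(9, 9,   9, 9))
  E <- expression_matrix(vals, rownames(vals), paste0("c", 1:4))
  res <- qc_filter_cells(E)
  # c1 expresses neither housekeeping gene; a bare 0.1 FPKM counts as expressed
  expect_identical(res$report$removed_cell_ids, "c1")
  expect_identical(res$matrix$cell_ids, c("c2", "c3", "c4"))
  expect_identical(res$report$n_retained + length(res$report$removed_cell_ids),
                   res$report$n_input_cells)
  expect_identical(res$matrix$gene_ids, E$gene_ids)

  # no-op when every cell expresses a housekeeping gene; idempotent
  again <- qc_filter_cells(res$matrix)
  expect_identical(again$report$n_retained, res$report$n_retained)
  expect_identical(again$matrix$values, res$matrix$values)
})

test_that("planted double-zero cells are removed in any number (brute-force check)", {
  set.seed(11)
  for (k in c(0, 3, 7)) {
    n <- 20
    vals <- matrix(stats::rexp(5 * n), 5, n,
                   dimnames = list(c("ACTB", "GAPDH", "g3", "g4", "g5"),
                                   sprintf("c%02d", 1:n)))
    dead <- sample(n, k)
    vals[1:2, dead] <- 0
    E <- expression_matrix(vals)
    res <- qc_filter_cells(E)
    brute <- colnames(vals)[vals["ACTB", ] == 0 & vals["GAPDH", ] == 0]
    expect_setequal(res$report$removed_cell_ids, brute)
  }
})

test_that("QC error paths: missing panel and empty result", {
  E <- expression_matrix(matrix(1, 2, 2), c("gA", "gB"), c("c1", "c2"))
  expect_error(qc_filter_cells(E), "housekeeping")
  dead <- expression_matrix(matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE),
                            c("ACTB", "GAPDH", "g3"), c("c1", "c2"))
  expect_error(qc_filter_cells(dead), "empty result")
})

test_that("quantile normalization matches the sort/average oracle, ties included", {
  set.seed(5)
  x <- matrix(stats::rnorm(9), 3, 3)
  expect_equal(somcell:::quantile_normalize(x), oracle_quantile_normalize(x))
  # heavy ties, including runs longer than two
  y <- matrix(c(1, 1, 1, 2, 0, 5, 3, 3, 4, 4, 4, 4), 4, 3)
  expect_equal(somcell:::quantile_normalize(y), oracle_quantile_normalize(y))
  # random 10 x 10 instances with duplicated values
  for (i in 1:5) {
    z <- matrix(sample(0:5, 100, replace = TRUE), 10, 10)
    expect_equal(somcell:::quantile_normalize(z), oracle_quantile_normalize(z))
  }
})

test_that("quantile normalization agrees with limma on tie-free input", {
  skip_if_not_installed("limma")
  set.seed(6)
  x <- matrix(stats::rnorm(60), 12, 5)
  expect_equal(unname(somcell:::quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
})

test_that("normalized matrices satisfy their invariants", {
  E <- tiny_expression()
  N <- normalize_expression(E)
  # every gene row centered
  expect_lt(max(abs(rowMeans(N$values))), 1e-9)
  # identical sorted value multisets across cells before centering
  pre <- somcell:::quantile_normalize(log10(E$values + 1))
  sorted <- unname(apply(pre, 2, sort))
  expect_equal(sorted, sorted[, c(1, 1:(ncol(sorted) - 1))],
               tolerance = 1e-12)
  # permuting genes between two cells leaves their sorted values identical
  Ep <- E
  Ep$values[, 2] <- Ep$values[sample(nrow(Ep$values)), 2]
  prep <- somcell:::quantile_normalize(log10(Ep$values + 1))
  expect_equal(unname(sort(prep[, 1])), unname(sort(prep[, 2])),
               tolerance = 1e-12)
})

test_that("normalization is invariant to cell order and handles edge cases", {
  E <- tiny_expression()
  N <- normalize_expression(E)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  Ep <- expression_matrix(E$values[, perm], E$gene_ids, E$cell_ids[perm])
  Np <- normalize_expression(Ep)
  expect_equal(Np$values, N$values[, perm])
  # constant matrix: all-zero output, no error
  const <- expression_matrix(matrix(2, 4, 3), paste0("g", 1:4), paste0("c", 1:3))
  expect_true(all(normalize_expression(const)$values == 0))
  expect_error(normalize_expression(
    expression_matrix(matrix(1, 5, 1), paste0("g", 1:5), "c1")), ">= 2 cells")
})

test_that("invariant-gene filter equals a per-row sd scan", {
  set.seed(9)
  x <- matrix(stats::rnorm(300), 100, 3)
  x[c(4, 40, 77), ] <- 5                       # constant rows
  N <- structure(list(values = x - rowMeans(x),
                      gene_ids = sprintf("g%03d", 1:100),
                      cell_ids = c("a", "b", "c")),
                 class = "normalized_matrix")
  out <- filter_invariant_genes(N, min_sd = 0)
  keep <- apply(N$values, 1, stats::sd) > 0
  expect_identical(out$gene_ids, N$gene_ids[keep])
  expect_identical(out$values, N$values[keep, ])
  # vacuous threshold keeps everything; degenerate case errors
  expect_identical(filter_invariant_genes(N, min_sd = -1)$gene_ids, N$gene_ids)
  allconst <- structure(list(values = matrix(0, 3, 3),
                             gene_ids = paste0("g", 1:3),
                             cell_ids = paste0("c", 1:3)),
                        class = "normalized_matrix")
  expect_error(filter_invariant_genes(allconst), "all genes removed")
})
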