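test_that("GMT parsing follows the standard dialect", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2",
               "S2\tanother\tg1\tg1\tg2",
               "S3\tna\tg9"), gmt)
  sets <- read_gmt(gmt)
  expect_length(sets, 3)
  expect_setequal(sets$S1$gene_ids, c("g1", "g2"))
  # duplicate members collapse
  expect_length(sets$S2$gene_ids, 2)
  expect_identical(sets$S3$gene_ids, "g9")
  # a memberless line is a parse error naming the line
  writeLines(c("S1\tdesc\tg1", "BAD\tdesc"), gmt)
  expect_error(read_gmt(gmt), "line 2")
  # round trip
  ok <- list(gene_set("A", c("x", "y")), gene_set("B", "z"))
  write_gmt(ok, gmt)
  back <- read_gmt(gmt)
  expect_setequal(back$A$gene_ids, c("x", "y"))
  expect_identical(back$B$gene_ids, "z")
})

test_that("Fisher enrichment equals exhaustive hypergeometric enumeration", {
  # every (universe, set, spot, overlap) shape with universe <= 25
  set.seed(23)
  for (i in 1:40) {
    N <- sample(5:25, 1)
    universe <- sprintf("u%02d", 1:N)
    K <- sample(1:N, 1)
    n_spot <- sample(1:N, 1)
    setg <- sample(universe, K)
    spotg <- sample(universe, n_spot)
    res <- fisher_enrichment(spotg, gene_set("s", setg), universe)
    a <- length(intersect(spotg, setg))
    expect_equal(res$p, oracle_fisher_p(a, K, N, n_spot), tolerance = 1e-12)
    expect_equal(res$a + res$b + res$c + res$d, N)
  }
})

test_that("Fisher enrichment agrees with fisher.test and handles edge tables", {
  universe <- sprintf("u%02d", 1:20)
  setg <- universe[1:5]
  res <- fisher_enrichment(universe[1:5], gene_set("s", setg), universe)
  # perfect overlap of 5 from 5 drawn out of 20: p = 1 / choose(20, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  ft <- stats::fisher.test(matrix(c(res$a, res$b, res$c, res$d), 2,
                                  byrow = TRUE), alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-9)
  # spot = set = universe: the test cannot discriminate, p = 1
  expect_equal(fisher_enrichment(universe, gene_set("s", universe),
                                 universe)$p, 1)
  # zero overlap: right tail includes the observed table, p = 1
  expect_equal(fisher_enrichment(universe[1:5],
                                 gene_set("s", universe[6:10]),
                                 universe)$p, 1)
  # continuity-corrected odds ratio when a cell is empty
  r0 <- fisher_enrichment(universe[1:5], gene_set("s", universe[6:10]),
                          universe)
  expect_equal(r0$odds_ratio, (0.5 * 10.5) / (5.5 * 5.5))
  expect_error(fisher_enrichment(character(0), gene_set("s", "x"),
                                 character(0)), "empty universe")
  expect_error(fisher_enrichment("zz", gene_set("s", "x"), universe),
               "outside the universe")
})

test_that("GSZ implements the variance-shrunken standardized set sum", {
  set.seed(25)
  vals <- matrix(stats::rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("c%02d", 1:10)))
  vals <- vals - rowMeans(vals)
  N <- structure(list(values = vals, gene_ids = sprintf("g%02d", 1:20),
                      cell_ids = sprintf("c%02d", 1:10)),
                 class = "normalized_matrix")
  setg <- c("g01", "g05", "g09", "g13")
  g <- gsz_profile(N, gene_set("s", setg), lambda_shrink = 10)
  # direct transcription of the formula
  n <- 4
  vg <- stats::var(as.vector(vals))
  brute <- vapply(1:10, function(c) {
    s2 <- (n * stats::var(vals[, c]) + 10 * vg) / (n + 10)
    sum(vals[setg, c]) / sqrt(n * s2)
  }, numeric(1))
  expect_equal(unname(g$scores), brute, tolerance = 1e-12)
  # linearity of the numerator: doubling set-gene values doubles the sum
  N2 <- N; N2$values[setg, ] <- 2 * N2$values[setg, ]
  expect_equal(colSums(N2$values[setg, ]), 2 * colSums(N$values[setg, ]))
  # full-gene set on a quantile-normalized, centered matrix: every cell
  # carries the same value multiset, so the set sum collapses to zero
  Nq <- normalize_expression(tiny_expression())
  gall <- gsz_profile(Nq, gene_set("all", Nq$gene_ids))
  expect_lt(max(abs(gall$scores)), 0.1)
  expect_error(gsz_profile(N, gene_set("none", c("zz1", "zz2"))),
               "no gene of set")
})

test_that("planted-program GSZ separates carriers and beats a permutation null", {
  run <- wtwt_run(wtwt_seeds()[1])
  N <- run$report$normalized
  truth <- run$d$truth
  g <- gsz_profile(N, run$d$gene_sets[["abc_aldh"]])
  carrier <- truth$rare_flags[N$cell_ids, "abc_aldh"]
  gap <- mean(g$scores[carrier]) - mean(g$scores[!carrier])
  expect_gt(gap, 3)
  # permutation null: random same-size sets never reach the observed gap
  set.seed(71)
  nulls <- vapply(1:100, function(i) {
    rnd <- sample(N$gene_ids, g$n_genes_used)
    gs <- gsz_profile(N, gene_set("r", rnd))$scores
    mean(gs[carrier]) - mean(gs[!carrier])
  }, numeric(1))
  expect_gt(gap, stats::quantile(nulls, 0.99))
})

test_that("GSZ flagging finds a separated subpopulation and stays silent otherwise", {
  set.seed(29)
  scores <- c(stats::rnorm(80, 0, 1), stats::rnorm(8, 9, 0.5))
  names(scores) <- sprintf("c%02d", 1:88)
  f <- flag_cells_by_gsz(scores)
  expect_setequal(names(which(f)), names(scores)[81:88])
  # unimodal scores: nothing flagged
  f0 <- flag_cells_by_gsz(stats::setNames(stats::rnorm(88), names(scores)))
  expect_equal(sum(f0), 0)
  expect_true(is.na(attr(f0, "threshold")))
})

test_that("gene-set maps conserve counts and localise planted programs", {
  set.seed(26)
  g2u <- stats::setNames(sample(1:25, 60, replace = TRUE),
                         sprintf("g%02d", 1:60))
  M <- structure(list(grid_rows = 5, grid_cols = 5,
                      codebook = matrix(0, 25, 4,
                                        dimnames = list(NULL, paste0("c", 1:4))),
                      gene_to_unit = g2u,
                      unit_coords = cbind(row = rep(1:5, each = 5),
                                          col = rep(1:5, times = 5)),
                      cell_ids = paste0("c", 1:4),
                      training_meta = list()), class = "som_model")
  # singleton set: one unit carries count 1
  m1 <- geneset_map(M, gene_set("one", "g07"))
  expect_equal(sum(m1$counts), 1)
  expect_equal(as.vector(t(m1$counts))[g2u[["g07"]]], 1)
  # full set: totals conserve the number of mapped genes
  mall <- geneset_map(M, gene_set("all", names(g2u)))
  expect_equal(sum(mall$counts), 60)
  # absent genes reported, not counted
  expect_message(mx <- geneset_map(M, gene_set("x", c("g01", "zz"))),
                 "absent")
  expect_equal(sum(mx$counts), 1)
  # on the wtwt preset the planted proliferation set concentrates inside
  # the spot that recovered it
  run <- wtwt_run(wtwt_seeds()[1])
  spots <- run$report$spots
  sp <- best_spot_for_set(spots, run$d$gene_sets[["proliferation"]])
  gm <- geneset_map(run$report$som, run$d$gene_sets[["proliferation"]])
  inside <- sum(as.vector(t(gm$counts))[sp$unit_indices])
  expect_gte(inside / gm$n_present, 0.6)
})
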