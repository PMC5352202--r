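# Shared fixtures. The wtwt multi-seed pipeline runs are expensive, so
# they are computed once per test session and memoised in this
# environment; every acceptance block reuses the same runs.

.fixture_env <- new.env(parent = emptyenv())

# a tiny deterministic expression matrix for unit tests
tiny_expression <- function(n_genes = 30, n_cells = 8, seed = 7) {
  set.seed(seed)
  vals <- matrix(stats::rexp(n_genes * n_cells, rate = 0.2),
                 n_genes, n_cells)
  expression_matrix(vals,
                    gene_ids = sprintf("g%02d", seq_len(n_genes)),
                    cell_ids = sprintf("c%02d", seq_len(n_cells)))
}

# one wtwt preset run: generator output + pipeline report
wtwt_run <- function(seed) {
  key <- paste0("wtwt_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  d <- generate_synthetic(preset("wtwt", seed = seed))
  rep <- run_pipeline(preset_run_config(seed = seed), matrix = d$matrix)
  .fixture_env[[key]] <- list(d = d, report = rep)
  .fixture_env[[key]]
}

wtwt_seeds <- function() 401:410

# small two-program block matrix with orthogonal gene programs
block_matrix <- function(n_per_program = 40, n_cells = 20, seed = 3) {
  set.seed(seed)
  half <- n_cells / 2
  a <- cbind(matrix(stats::rnorm(n_per_program * half, 3, 0.3), ncol = half),
             matrix(stats::rnorm(n_per_program * half, 0, 0.3), ncol = half))
  b <- cbind(matrix(stats::rnorm(n_per_program * half, 0, 0.3), ncol = half),
             matrix(stats::rnorm(n_per_program * half, 3, 0.3), ncol = half))
  x <- rbind(a, b)
  rownames(x) <- sprintf("g%03d", seq_len(2 * n_per_program))
  colnames(x) <- sprintf("c%03d", seq_len(n_cells))
  structure(list(values = x - rowMeans(x), gene_ids = rownames(x),
                 cell_ids = colnames(x)), class = "normalized_matrix")
}
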