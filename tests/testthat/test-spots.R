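make_model <- function(codebook, rows, cols, gene_to_unit, cell_ids) {
  structure(list(grid_rows = rows, grid_cols = cols,
                 codebook = codebook,
                 gene_to_unit = gene_to_unit,
                 unit_coords = cbind(row = rep(seq_len(rows), each = cols),
                                     col = rep(seq_len(cols), times = rows)),
                 cell_ids = cell_ids,
                 training_meta = list(epochs = 0, seed = 0,
                                      quantization_error = 0)),
            class = "som_model")
}

portrait_from <- function(m) {
  structure(list(values = m, label = "toy", kind = "summary"),
            class = "portrait")
}

test_that("summary map takes per-unit quantiles across cells", {
  cb <- matrix(c(0, 1, 2, 3,
                 5, 5, 5, 5,
                 -1, 0, 1, 2,
                 10, 0, 0, 0), 4, 4, byrow = TRUE)
  M <- make_model(cb, 2, 2, stats::setNames(1:4, paste0("g", 1:4)),
                  paste0("c", 1:4))
  # q = 1 gives per-unit maxima
  expect_equal(portrait_vector(summary_overexpression_map(M, q = 1)),
               apply(cb, 1, max))
  # arbitrary quantile equals the direct per-row oracle
  for (q in c(0.25, 0.5, 0.98)) {
    expect_equal(portrait_vector(summary_overexpression_map(M, q = q)),
                 apply(cb, 1, stats::quantile, probs = q, names = FALSE))
  }
  # constant codebook gives a constant map
  Mc <- make_model(matrix(3, 4, 4), 2, 2,
                   stats::setNames(1:4, paste0("g", 1:4)), paste0("c", 1:4))
  expect_equal(diff(range(summary_overexpression_map(Mc, 0.9)$values)), 0)
  expect_error(summary_overexpression_map(M, q = 0), "\\(0, 1]")
  expect_error(summary_overexpression_map(M, q = 1.2), "\\(0, 1]")
})

test_that("component segmentation finds plateaus, respects gaps and min size", {
  v <- matrix(0, 8, 8)
  v[2:4, 2:4] <- 1                       # single 3x3 plateau
  sp <- detect_spots(portrait_from(v), threshold_quantile = 0.9, min_units = 5)
  expect_length(sp, 1)
  expect_equal(nrow(sp[[1]]$unit_coords), 9)
  expect_identical(sp[[1]]$label, "A")

  # two plateaus separated by a background row are two spots ...
  v2 <- matrix(0, 8, 8)
  v2[1:2, 1:8] <- 1; v2[4:5, 1:8] <- 0.9
  sp2 <- detect_spots(portrait_from(v2), threshold_quantile = 0.5, min_units = 5)
  expect_length(sp2, 2)
  expect_identical(sp2[[1]]$label, "A")          # labelled by peak value
  expect_equal(sp2[[1]]$peak_value, 1)
  # ... and filling the gap merges them into one
  v3 <- v2; v3[3, ] <- 0.9
  expect_length(detect_spots(portrait_from(v3), 0.5, 5), 1)

  # uniform portrait: everything is foreground, one grid-covering spot
  spu <- detect_spots(portrait_from(matrix(1, 5, 5)), 0.9, 5)
  expect_length(spu, 1)
  expect_equal(nrow(spu[[1]]$unit_coords), 25)

  # nothing large enough: empty list, not an error
  v4 <- matrix(0, 8, 8); v4[1, 1:3] <- 1
  expect_length(detect_spots(portrait_from(v4), 0.98, 5), 0)
})

test_that("component labelling matches the brute-force flood fill on random grids", {
  set.seed(21)
  for (i in 1:8) {
    fg <- matrix(stats::runif(64) < 0.4, 8, 8)
    got <- somcell:::label_components_8(fg)
    want <- oracle_components8(fg)
    # same partition up to label names
    expect_equal(got > 0, want > 0)
    expect_equal(length(unique(got[got > 0])), length(unique(want[want > 0])))
    for (k in unique(want[want > 0])) {
      expect_length(unique(got[want == k]), 1)
    }
  }
})

test_that("watershed splits adjacent peaks but merges low-prominence ones", {
  v <- matrix(0, 7, 7)
  v[2:6, 2] <- c(1, 2, 3, 2, 1)          # ridge with peak 3
  v[2:6, 5] <- c(1, 2, 2.8, 2, 1)        # second ridge, saddle via col 3-4
  v[2:6, 3:4] <- 0.8
  p <- portrait_from(v)
  two <- detect_spots(p, threshold_quantile = 0.5, min_units = 3,
                      method = "watershed", tolerance = 0.5)
  expect_length(two, 2)
  # tolerance above both prominences merges everything into one spot
  one <- detect_spots(p, threshold_quantile = 0.5, min_units = 3,
                      method = "watershed", tolerance = 5)
  expect_length(one, 1)
  # watershed with huge tolerance reduces to connected components
  expect_equal(nrow(one[[1]]$unit_coords),
               nrow(detect_spots(p, 0.5, 3)[[1]]$unit_coords))
})

test_that("watershed agrees with the EBImage reference on a random landscape", {
  skip_if_not_installed("EBImage")
  set.seed(33)
  base <- matrix(0, 12, 12)
  base[3:5, 3:5] <- 2; base[8:10, 8:10] <- 3
  v <- base + matrix(stats::runif(144, 0, 0.1), 12, 12)
  fg <- v >= 1
  got <- somcell:::watershed_label(v, fg, tolerance = 0.5)
  img <- v - min(v); img[!fg] <- 0
  ref <- EBImage::watershed(img, tolerance = 0.5)
  expect_equal(length(unique(got[got > 0])), length(unique(ref[ref > 0])))
  for (k in unique(ref[ref > 0])) {
    expect_length(unique(got[ref == k & got > 0]), 1)
  }
})

test_that("spot gene ranking follows Pearson correlation with the spot profile", {
  set.seed(12)
  cells <- paste0("c", 1:10)
  cb <- matrix(stats::rnorm(40), 4, 10, dimnames = list(NULL, cells))
  cb[1, ] <- seq(-1, 1, length.out = 10)   # spot unit profile
  g2u <- stats::setNames(rep(1L, 10), paste0("g", 1:10))
  M <- make_model(cb, 2, 2, g2u, cells)
  spot <- structure(list(label = "A", unit_coords = cbind(1, 1),
                         unit_indices = 1L, peak_value = 1),
                    class = "spot_module")
  prof <- cb[1, ]
  vals <- t(vapply(1:10, function(i) prof * (11 - i) +
                     stats::rnorm(10, 0, 0.3), numeric(10)))
  vals[1, ] <- prof                        # exact copy: r = 1, rank 1
  vals[10, ] <- -prof                      # negated: r = -1, rank last
  N <- structure(list(values = vals, gene_ids = paste0("g", 1:10),
                      cell_ids = cells), class = "normalized_matrix")
  out <- attach_spot_genes(M, N, spot)
  r_brute <- apply(vals, 1, function(g) stats::cor(g, prof))
  expect_identical(out$member_genes$gene_id,
                   paste0("g", order(r_brute, decreasing = TRUE)))
  expect_equal(out$member_genes$r, sort(r_brute, decreasing = TRUE))
  expect_equal(out$member_genes$r[1], 1)
  expect_equal(out$member_genes$r[10], -1)
  expect_equal(unname(out$profile), unname(prof))
  # spot with no genes: empty members plus a warning
  spot2 <- structure(list(label = "B", unit_coords = cbind(2, 2),
                          unit_indices = 4L, peak_value = 0),
                     class = "spot_module")
  expect_warning(out2 <- attach_spot_genes(M, N, spot2), "no member genes")
  expect_equal(nrow(out2$member_genes), 0)
})

test_that("per-cell spot counts equal the direct per-cell evaluation", {
  set.seed(14)
  cells <- paste0("c", 1:12)
  cb <- matrix(stats::rnorm(16 * 12), 16, 12, dimnames = list(NULL, cells))
  g2u <- stats::setNames(sample(1:16, 30, replace = TRUE), paste0("g", 1:30))
  M <- make_model(cb, 4, 4, g2u, cells)
  spots <- list(
    structure(list(label = "A", unit_coords = cbind(1, 1:3),
                   unit_indices = 1:3, peak_value = 3), class = "spot_module"),
    structure(list(label = "B", unit_coords = cbind(2, 1:2),
                   unit_indices = 5:6, peak_value = 2), class = "spot_module"),
    structure(list(label = "C", unit_coords = cbind(4, 1:4),
                   unit_indices = 13:16, peak_value = 1), class = "spot_module"))
  got <- spots_per_cell(M, spots, cell_threshold_quantile = 0.9)
  brute <- vapply(cells, function(cc) {
    thr <- stats::quantile(cb[, cc], 0.9)
    sum(vapply(spots, function(s) mean(cb[s$unit_indices, cc]) > thr,
               logical(1)))
  }, numeric(1))
  expect_equal(stats::setNames(got$n_spots, got$cell_id), brute)
  # a spatially constant portrait can never beat its own upper quantile
  Mc <- make_model(matrix(1, 16, 12, dimnames = list(NULL, cells)), 4, 4,
                   g2u, cells)
  expect_true(all(spots_per_cell(Mc, spots)$n_spots == 0))
  expect_error(spots_per_cell(M, list()), "at least one spot")
})
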