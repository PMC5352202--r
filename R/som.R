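#' Train a self-organizing map of metagenes
#'
#' Genes are the mapped items: each gene's expression profile across
#' cells is a point in R^(n_cells), and the map condenses those profiles
#' into `grid_rows * grid_cols` metagene profiles arranged on a quadratic
#' grid (2,500 metagenes on the default 50 x 50 grid). Training is batch
#' SOM: unit weight vectors are initialised on the plane spanned by the
#' first two principal components of the gene cloud, and each epoch every
#' gene is assigned to its Euclidean best-matching unit (BMU) before all
#' units are recomputed as Gaussian-neighbourhood weighted means. The
#' neighbourhood radius decays linearly from `max(grid_rows, grid_cols)/2`
#' to 1 over the epochs. Batch updates make the fit independent of gene
#' order; the seed only pins principal-component sign conventions and BMU
#' tie-breaks, so a fixed seed gives a bit-identical codebook.
#'
#' @param N A `normalized_matrix` from [normalize_expression()].
#' @param grid_rows,grid_cols Grid dimensions (default 50 x 50).
#' @param epochs Number of batch epochs (default 30).
#' @param seed Integer seed (mandatory).
#' @param trace Record the per-epoch BMU assignment and quantization
#'   error in `training_meta$bmu_history` / `$qe_history` (memory-heavy;
#'   default `FALSE`).
#' @return A `som_model`: `grid_rows`, `grid_cols`, `codebook` (units x
#'   cells; row `u` is metagene `u`'s profile), `gene_to_unit` (named
#'   integer vector, row-major unit indices), `unit_coords` (units x 2),
#'   `cell_ids`, `training_meta` (epochs, seed, final quantization error).
#' @export
train_som <- function(N, grid_rows = 50, grid_cols = 50, epochs = 30,
                      seed, trace = FALSE) {
  stopifnot(inherits(N, "normalized_matrix"))
  if (missing(seed)) stop("seed is mandatory")
  X <- N$values                       # genes x cells
  if (ncol(X) < 2) stop("SOM training needs >= 2 cells")
  if (any(!is.finite(X))) stop("non-finite values in input")
  n_units <- grid_rows * grid_cols
  if (nrow(X) < n_units) {
    warning("fewer genes (", nrow(X), ") than map units (", n_units,
            "); consider a smaller grid")
  }
  set.seed(seed)

  # Row-major unit layout: unit u sits at (row, col) with u = (row-1)*cols + col.
  coords <- cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                  col = rep(seq_len(grid_cols), times = grid_rows))
  grid_d2 <- as.matrix(stats::dist(coords))^2

  W <- som_linear_init(X, grid_rows, grid_cols, coords)

  radius_max <- max(grid_rows, grid_cols) / 2
  radii <- if (epochs == 1) 1 else
    radius_max - (radius_max - 1) * (seq_len(epochs) - 1) / (epochs - 1)

  xsq <- rowSums(X^2)
  bmu_history <- if (trace) vector("list", epochs) else NULL
  qe_history <- if (trace) numeric(epochs) else NULL
  bmu <- NULL
  for (e in seq_len(epochs)) {
    d2 <- outer(xsq, rowSums(W^2), "+") - 2 * X %*% t(W)
    bmu <- max.col(-d2, ties.method = "first")
    if (trace) {
      bmu_history[[e]] <- bmu
      qe_history[e] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu)], 0)))
    }
    H <- exp(-grid_d2 / (2 * radii[e]^2))       # units x units neighbourhood
    S <- rowsum(X, group = bmu)                 # per-BMU sums
    counts <- tabulate(bmu, nbins = n_units)
    Sfull <- matrix(0, n_units, ncol(X))
    Sfull[as.integer(rownames(S)), ] <- S
    W <- (H %*% Sfull) / as.vector(H %*% counts)
  }
  d2 <- outer(xsq, rowSums(W^2), "+") - 2 * X %*% t(W)
  bmu <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu)], 0)))

  dimnames(W) <- list(NULL, N$cell_ids)
  names(bmu) <- N$gene_ids
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols,
    codebook = W,
    gene_to_unit = bmu,
    unit_coords = coords,
    cell_ids = N$cell_ids,
    training_meta = list(epochs = epochs, seed = seed,
                         quantization_error = qe,
                         bmu_history = bmu_history,
                         qe_history = qe_history)
  ), class = "som_model")
}

# Linear initialisation on the first two principal components of the gene
# cloud; sign convention: each component's largest-magnitude loading is
# made positive, so the layout is reproducible.
som_linear_init <- function(X, grid_rows, grid_cols, coords) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = 2)
  v <- sv$v
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  sdev <- sv$d[seq_len(ncol(v))] / sqrt(max(1, nrow(X) - 1))
  if (ncol(v) < 2) {                  # 2-cell corner case: one component
    v <- cbind(v, 0); sdev <- c(sdev, 0)
  }
  a <- if (grid_rows == 1) 0 else seq(-2, 2, length.out = grid_rows)
  b <- if (grid_cols == 1) 0 else seq(-2, 2, length.out = grid_cols)
  t(vapply(seq_len(nrow(coords)), function(u) {
    mu + a[coords[u, "row"]] * sdev[1] * v[, 1] +
         b[coords[u, "col"]] * sdev[2] * v[, 2]
  }, numeric(ncol(X))))
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d grid (%d metagenes), %d genes, %d cells\n",
              x$grid_rows, x$grid_cols, x$grid_rows * x$grid_cols,
              length(x$gene_to_unit), length(x$cell_ids)))
  cat(sprintf("  epochs = %d, seed = %s, quantization error = %.4g\n",
              x$training_meta$epochs, format(x$training_meta$seed),
              x$training_meta$quantization_error))
  invisible(x)
}

new_portrait <- function(values, model, label, kind) {
  m <- matrix(values, nrow = model$grid_rows, ncol = model$grid_cols,
              byrow = TRUE)              # row-major unit order
  structure(list(values = m, label = label, kind = kind),
            class = "portrait")
}

#' @export
print.portrait <- function(x, ...) {
  cat(sprintf("portrait [%s] '%s': %d x %d, range [%.3g, %.3g]\n",
              x$kind, x$label, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Single-cell expression portrait
#'
#' A cell's portrait is its component of every metagene: column `cell_id`
#' of the codebook reshaped onto the grid. Pure reshaping, no
#' recomputation.
#'
#' @param M A `som_model`.
#' @param cell_id Cell identifier present in the model.
#' @return A `portrait` (values: grid_rows x grid_cols, kind
#'   `"single-cell"`).
#' @export
cell_portrait <- function(M, cell_id) {
  stopifnot(inherits(M, "som_model"))
  if (!cell_id %in% M$cell_ids) stop("unknown cell id: ", cell_id)
  new_portrait(M$codebook[, cell_id], M, cell_id, "single-cell")
}

#' Mean expression portrait over a set of cells
#'
#' Element-wise mean of the member cells' portraits; used for group-mean
#' portraits and the all-cell summary portrait.
#'
#' @param M A `som_model`.
#' @param cell_ids Non-empty character vector of cell ids.
#' @param label Label attached to the portrait.
#' @return A `portrait` of kind `"group-mean"`, or `"summary"` when
#'   `cell_ids` covers every cell in the model.
#' @export
mean_portrait <- function(M, cell_ids, label = "mean") {
  stopifnot(inherits(M, "som_model"))
  if (length(cell_ids) == 0) stop("empty cell list")
  missing_ids <- setdiff(cell_ids, M$cell_ids)
  if (length(missing_ids)) stop("unknown cell ids: ",
                                paste(missing_ids, collapse = ", "))
  kind <- if (setequal(cell_ids, M$cell_ids)) "summary" else "group-mean"
  vals <- rowMeans(M$codebook[, cell_ids, drop = FALSE])
  new_portrait(vals, M, label, kind)
}

#' Flatten a portrait to the row-major unit vector
#' @param P A `portrait`.
#' @return Numeric vector of length grid_rows * grid_cols in unit order.
#' @export
portrait_vector <- function(P) {
  stopifnot(inherits(P, "portrait"))
  as.vector(t(P$values))
}

#' Persist a trained map as plain text
#'
#' Writes `codebook.tsv` (units x cells), `gene_to_unit.tsv` and
#' `training_meta.json` into `dir`.
#'
#' @param M A `som_model`.
#' @param dir Output directory (created if absent).
#' @export
write_som_model <- function(M, dir) {
  stopifnot(inherits(M, "som_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cb <- data.frame(unit = seq_len(nrow(M$codebook)), M$unit_coords,
                   M$codebook, check.names = FALSE)
  utils::write.table(cb, file.path(dir, "codebook.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g2u <- data.frame(gene_id = names(M$gene_to_unit),
                    unit = as.integer(M$gene_to_unit))
  utils::write.table(g2u, file.path(dir, "gene_to_unit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- M$training_meta[c("epochs", "seed", "quantization_error")]
  meta$grid <- c(M$grid_rows, M$grid_cols)
  jsonlite::write_json(meta, file.path(dir, "training_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
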