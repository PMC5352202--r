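#' Housekeeping-based cell quality filter
#'
#' Retains a cell if and only if at least one housekeeping gene is
#' expressed (strictly > 0 FPKM) in that cell; cells expressing neither
#' housekeeping gene are chamber failures and are removed. The gene set
#' is never touched.
#'
#' @param E An [expression_matrix()].
#' @param housekeeping Gene ids used as the detection panel. Defaults to
#'   the canonical ACTB/GAPDH pair.
#' @return A list with `matrix` (the filtered [expression_matrix()]) and
#'   `report`, a `qc_report` recording `n_input_cells`, `n_retained`,
#'   `removed_cell_ids` and the housekeeping genes actually found.
#' @export
qc_filter_cells <- function(E, housekeeping = c("ACTB", "GAPDH")) {
  stopifnot(inherits(E, "expression_matrix"))
  present <- intersect(housekeeping, E$gene_ids)
  if (length(present) == 0) {
    stop("none of the housekeeping genes (",
         paste(housekeeping, collapse = ", "), ") found in the matrix")
  }
  hk <- E$values[present, , drop = FALSE]
  keep <- colSums(hk > 0) > 0
  if (!any(keep)) stop("QC filter removed every cell: empty result")
  report <- structure(list(
    n_input_cells = ncol(E$values),
    n_retained = sum(keep),
    removed_cell_ids = E$cell_ids[!keep],
    housekeeping_genes = present
  ), class = "qc_report")
  filtered <- expression_matrix(E$values[, keep, drop = FALSE],
                                E$gene_ids, E$cell_ids[keep])
  list(matrix = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d cells retained (%d removed; panel: %s)\n",
              x$n_retained, x$n_input_cells, length(x$removed_cell_ids),
              paste(x$housekeeping_genes, collapse = ", ")))
  invisible(x)
}

#' Quantile normalization across cells
#'
#' Replaces every cell's values by the rank-wise means of the sorted
#' columns, so that afterwards all cells share one value multiset. Ties
#' within a cell receive the mean of the rank-means over their tied rank
#' positions.
#'
#' @param x Numeric matrix (rows = genes, columns = cells).
#' @return Matrix of the same shape.
#' @keywords internal
quantile_normalize <- function(x) {
  sorted <- apply(x, 2, sort, method = "radix")
  ref <- rowMeans(sorted)                       # rank-wise target values
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j], method = "radix")
    v <- x[o, j]
    run <- cumsum(c(TRUE, diff(v) != 0))        # runs of tied values
    out[o, j] <- stats::ave(ref, run, FUN = mean)
  }
  out
}

#' Normalize and centralize an expression matrix
#'
#' The portrayal pipeline's normalization: (i) optional `log10(x + 1)`
#' transform of the FPKM values, (ii) quantile normalization across cells,
#' (iii) gene-wise centering (centralization), so that every gene row has
#' mean zero and every cell carries the same value distribution up to the
#' centering step.
#'
#' @param E An [expression_matrix()].
#' @param log_transform Apply `log10(x + 1)` first (default `TRUE`;
#'   recommended for FPKM-scale data, whose dynamic range otherwise
#'   destabilises map training).
#' @return A `normalized_matrix`: list with `values` (genes x cells,
#'   log-scale, gene-centered), `gene_ids`, `cell_ids`.
#' @export
normalize_expression <- function(E, log_transform = TRUE) {
  stopifnot(inherits(E, "expression_matrix"))
  if (ncol(E$values) < 2) stop("normalization needs >= 2 cells")
  if (nrow(E$values) < 2) stop("normalization needs >= 2 genes")
  x <- E$values
  if (any(is.na(x))) stop("NaN/NA values in input")
  if (log_transform) x <- log10(x + 1)
  x <- quantile_normalize(x)
  x <- x - rowMeans(x)
  structure(list(values = x, gene_ids = E$gene_ids, cell_ids = E$cell_ids),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (log-scale, gene-centered)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Drop invariant genes
#'
#' Removes genes whose standard deviation across cells is `<= min_sd`.
#' Zero-variance rows carry no information and degenerate map training.
#'
#' @param N A `normalized_matrix`.
#' @param min_sd Threshold on the per-gene standard deviation (default 0:
#'   only exactly-constant genes are dropped).
#' @return A `normalized_matrix` restricted to the surviving genes.
#' @export
filter_invariant_genes <- function(N, min_sd = 0) {
  stopifnot(inherits(N, "normalized_matrix"))
  sds <- apply(N$values, 1, stats::sd)
  keep <- sds > min_sd
  if (!any(keep)) stop("all genes removed by invariance filter (min_sd = ",
                       min_sd, ")")
  structure(list(values = N$values[keep, , drop = FALSE],
                 gene_ids = N$gene_ids[keep],
                 cell_ids = N$cell_ids),
            class = "normalized_matrix")
}
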