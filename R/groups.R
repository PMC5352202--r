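#' Pairwise portrait correlation matrix
#'
#' Mutual similarity of single-cell expression landscapes: Pearson
#' correlation between the flattened portraits of every pair of cells
#' (equivalently between codebook columns). A zero-variance portrait
#' gets correlation 0 with a warning.
#'
#' @param M A `som_model`.
#' @return A `correlation_matrix`: `r` (cells x cells, symmetric,
#'   diagonal 1) and `cell_ids`.
#' @export
portrait_correlations <- function(M) {
  stopifnot(inherits(M, "som_model"))
  if (length(M$cell_ids) < 2) stop("need >= 2 cells")
  sds <- apply(M$codebook, 2, stats::sd)
  r <- suppressWarnings(stats::cor(M$codebook))
  if (any(sds == 0)) {
    warning("zero-variance portrait(s): ",
            paste(M$cell_ids[sds == 0], collapse = ", "),
            "; correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(M$cell_ids, M$cell_ids)
  structure(list(r = r, cell_ids = M$cell_ids), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d cells, r in [%.3f, %.3f]\n",
              length(x$cell_ids), min(x$r), max(x$r)))
  invisible(x)
}

#' Discover cell groups from portrait correlations
#'
#' Hierarchical agglomerative clustering on the correlation distance
#' d = 1 - r. With `k = "auto"` the number of groups is the value in
#' `k_range` that maximises the overall mean silhouette width (computed
#' on d). Groups are renumbered by decreasing size, so group 1 is always
#' the largest.
#'
#' @param C A `correlation_matrix`.
#' @param k Integer number of groups, or `"auto"` (default).
#' @param k_range Candidate k values for auto selection (default 2:8).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `cell_grouping`: `assignment` (named integer vector), `k`,
#'   `silhouette` (named per-cell widths), `mean_silhouette` (per group),
#'   `overall_silhouette`, `hclust` (the dendrogram object).
#' @export
cluster_cells <- function(C, k = "auto", k_range = 2:8,
                          linkage = c("average", "complete")) {
  stopifnot(inherits(C, "correlation_matrix"))
  linkage <- match.arg(linkage)
  n <- length(C$cell_ids)
  d <- stats::as.dist(1 - C$r)
  if (all(d < 1e-12)) {                # all portraits identical
    warning("all pairwise distances are zero; returning a single group ",
            "with silhouette widths set to 0")
    sil <- stats::setNames(rep(0, n), C$cell_ids)
    return(structure(list(
      assignment = stats::setNames(rep(1L, n), C$cell_ids), k = 1L,
      silhouette = sil, mean_silhouette = c(`1` = 0),
      overall_silhouette = 0, hclust = NULL), class = "cell_grouping"))
  }
  hc <- stats::hclust(d, method = linkage)
  if (identical(k, "auto")) {
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(k_range) == 0) stop("empty k_range for ", n, " cells")
    score <- vapply(k_range, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- k_range[which.max(score)]
  }
  if (k > n) stop("k (", k, ") exceeds number of cells (", n, ")")
  cl <- stats::cutree(hc, k = k)
  # renumber groups by decreasing size; stable tie-break on old label
  sizes <- table(cl)
  new_id <- stats::setNames(rank(-as.vector(sizes), ties.method = "first"),
                            names(sizes))
  cl <- stats::setNames(as.integer(new_id[as.character(cl)]), C$cell_ids)
  if (k == 1) {
    sil <- stats::setNames(rep(0, n), C$cell_ids)
  } else {
    so <- cluster::silhouette(cl, d)
    sil <- stats::setNames(so[, "sil_width"], C$cell_ids)
  }
  structure(list(
    assignment = cl, k = as.integer(k),
    silhouette = sil,
    mean_silhouette = tapply(sil, cl, mean),
    overall_silhouette = mean(sil),
    hclust = hc), class = "cell_grouping")
}

#' @export
print.cell_grouping <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("cell_grouping: k = %d (%s cells), mean silhouette = %.3f\n",
              x$k, paste(sizes, collapse = "/"), x$overall_silhouette))
  invisible(x)
}

#' Cell similarity network
#'
#' Undirected graph with one node per cell and an edge wherever the
#' portrait correlation reaches `edge_threshold`. Purely presentational:
#' group assignment never depends on it.
#'
#' @param C A `correlation_matrix`.
#' @param edge_threshold Minimum r for an edge (default 0.3).
#' @param grouping Optional `cell_grouping`; stored as a node attribute.
#' @return An igraph graph with edge attribute `weight` (= r) and, when
#'   given, node attribute `group`.
#' @export
build_network <- function(C, edge_threshold = 0.3, grouping = NULL) {
  stopifnot(inherits(C, "correlation_matrix"))
  adj <- C$r >= edge_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  if (nrow(ends)) {
    igraph::E(g)$weight <- C$r[cbind(ends[, 1], ends[, 2])]
  }
  if (!is.null(grouping)) {
    igraph::V(g)$group <- as.integer(grouping$assignment[igraph::V(g)$name])
  }
  g
}

#' Identify the cell group whose portraits peak in a spot
#'
#' For every group, averages the group members' portraits over the
#' spot's units and returns the group with the highest mean — the group
#' that "owns" the spot (e.g. the proliferative group for the
#' cell-cycle spot).
#'
#' @param M A `som_model`.
#' @param grouping A `cell_grouping`.
#' @param spot A `spot_module`.
#' @return Integer group index.
#' @export
group_for_spot <- function(M, grouping, spot) {
  stopifnot(inherits(M, "som_model"), inherits(grouping, "cell_grouping"),
            inherits(spot, "spot_module"))
  spot_mean <- colMeans(M$codebook[spot$unit_indices, , drop = FALSE])
  by_group <- tapply(spot_mean[names(grouping$assignment)],
                     grouping$assignment, mean)
  as.integer(names(by_group)[which.max(by_group)])
}

#' Export a grouping and its silhouette data as TSV
#' @param grouping A `cell_grouping`.
#' @param path Output TSV path.
#' @export
write_grouping_tsv <- function(grouping, path) {
  df <- data.frame(cell_id = names(grouping$assignment),
                   group = as.integer(grouping$assignment),
                   silhouette = as.numeric(grouping$silhouette),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
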