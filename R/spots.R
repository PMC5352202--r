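#' Summary over-expression map
#'
#' Condenses all cells into one portrait showing where over-expression
#' happens anywhere in the population: unit (i,j) carries the `q`-th
#' quantile of that metagene's value across cells. A high quantile (the
#' 0.98 default) keeps units that are strongly expressed in only a small
#' subpopulation visible, which a plain mean would wash out.
#'
#' @param M A `som_model`.
#' @param q Quantile in (0, 1]; `q = 1` gives per-unit maxima.
#' @return A `portrait` of kind `"summary"`.
#' @export
summary_overexpression_map <- function(M, q = 0.98) {
  stopifnot(inherits(M, "som_model"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    stop("q must lie in (0, 1]")
  }
  vals <- apply(M$codebook, 1, stats::quantile, probs = q, names = FALSE)
  new_portrait(vals, M, sprintf("q%.2f over-expression", q), "summary")
}

# Tolerance-merged grayscale watershed on the foreground units: units
# are flooded in decreasing value order; a unit touching no labelled
# region starts one (a local maximum), a unit touching several is a
# saddle, where any adjacent region whose peak rises less than
# `tolerance` above the saddle is merged into the highest-peaked
# neighbour. Returns an integer label matrix (0 = background).
watershed_label <- function(v, fg, tolerance) {
  nr <- nrow(v); ncl <- ncol(v)
  idx <- which(fg)
  ord <- idx[order(v[idx], decreasing = TRUE)]
  lab <- matrix(0L, nr, ncl)
  parent <- integer(0); peak <- numeric(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nlab <- 0L
  for (p in ord) {
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    nb <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni < 1 || nj < 1 || ni > nr || nj > ncl) next
      if (lab[ni, nj] > 0L) nb <- c(nb, find(lab[ni, nj]))
    }
    nb <- unique(nb)
    if (length(nb) == 0) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      peak[nlab] <- v[p]
      lab[i, j] <- nlab
    } else if (length(nb) == 1) {
      lab[i, j] <- nb
    } else {
      keep <- nb[which.max(peak[nb])]
      merge_these <- nb[nb != keep & peak[nb] - v[p] < tolerance]
      parent[merge_these] <- keep
      lab[i, j] <- keep
    }
  }
  if (nlab > 0) {
    for (k in seq_len(nlab)) parent[k] <- find(k)
    pos <- lab > 0L
    lab[pos] <- parent[lab[pos]]
  }
  lab
}

# 8-connected component labelling of a logical grid by breadth-first
# flood fill. Returns an integer matrix (0 = background).
label_components_8 <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  cur <- 0L
  for (i in seq_len(nrow(fg))) for (j in seq_len(ncol(fg))) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || nj < 1 || ni > nrow(fg) || nj > ncol(fg)) next
        if (fg[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

#' Segment over-expression spot modules from a portrait
#'
#' Units whose value reaches the `threshold_quantile` of all unit values
#' are foreground; 8-connected foreground components with at least
#' `min_units` units become spot modules, labelled A, B, C, ... by
#' decreasing peak value. Spots are pairwise disjoint by construction.
#'
#' With `method = "watershed"` each foreground component is further
#' split into the catchment basins of its local maxima (standard
#' grayscale watershed); `tolerance` is the minimum prominence — basins
#' whose peak rises less than `tolerance` above the saddle to a higher
#' neighbour are merged into it. This separates adjacent co-regulated
#' modules that a plain threshold would fuse into one plateau.
#'
#' @param P A `portrait` (typically from [summary_overexpression_map()]).
#' @param threshold_quantile Foreground quantile of the unit values
#'   (default 0.90).
#' @param min_units Minimum component size (default 5).
#' @param method `"components"` (default) or `"watershed"`.
#' @param tolerance Watershed prominence threshold, in portrait value
#'   units (default 0.15).
#' @return List of `spot_module` objects: `label`, `unit_coords`
#'   (n x 2, grid row/col), `unit_indices` (row-major), `peak_value`;
#'   gene membership is attached later by [attach_spot_genes()]. Empty
#'   list when no component is large enough.
#' @export
detect_spots <- function(P, threshold_quantile = 0.90, min_units = 5,
                         method = c("components", "watershed"),
                         tolerance = 0.15) {
  stopifnot(inherits(P, "portrait"))
  method <- match.arg(method)
  v <- P$values
  if (any(!is.finite(v))) stop("portrait must be finite")
  thr <- stats::quantile(v, probs = threshold_quantile, names = FALSE)
  fg <- v >= thr
  lab <- if (method == "components") label_components_8(fg) else
    watershed_label(v, fg, tolerance)
  spots <- list()
  for (comp in setdiff(sort(unique(as.vector(lab))), 0L)) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < min_units) next
    spots[[length(spots) + 1]] <- list(
      unit_coords = unname(idx),
      peak_value = max(v[idx]))
  }
  if (length(spots) == 0) return(list())
  ord <- order(vapply(spots, `[[`, numeric(1), "peak_value"),
               decreasing = TRUE)
  spots <- spots[ord]
  ncols <- ncol(v)
  for (s in seq_along(spots)) {
    spots[[s]]$label <- make_spot_label(s)
    cc <- spots[[s]]$unit_coords
    spots[[s]]$unit_indices <- (cc[, 1] - 1L) * ncols + cc[, 2]
    class(spots[[s]]) <- "spot_module"
  }
  spots
}

make_spot_label <- function(i) {
  if (i <= 26) LETTERS[i] else paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
}

#' @export
print.spot_module <- function(x, ...) {
  cat(sprintf("spot %s: %d units%s\n", x$label, nrow(x$unit_coords),
              if (!is.null(x$member_genes))
                sprintf(", %d member genes", nrow(x$member_genes)) else ""))
  invisible(x)
}

#' Attach and rank member genes of a spot
#'
#' A spot's member genes are exactly the genes whose best-matching unit
#' lies inside the spot. The spot profile is the mean of its metagene
#' profiles (one value per cell), and each member gene is ranked by
#' decreasing Pearson correlation between its expression profile and
#' that spot profile.
#'
#' @param M A `som_model`.
#' @param N The `normalized_matrix` the model was trained on.
#' @param spot A `spot_module` from [detect_spots()].
#' @return The spot with `profile` (named per-cell numeric) and
#'   `member_genes` (data.frame `gene_id`, `r`, sorted by decreasing `r`)
#'   filled in.
#' @export
attach_spot_genes <- function(M, N, spot) {
  stopifnot(inherits(M, "som_model"), inherits(N, "normalized_matrix"),
            inherits(spot, "spot_module"))
  if (any(spot$unit_indices < 1 | spot$unit_indices > nrow(M$codebook))) {
    stop("spot units outside the model grid")
  }
  profile <- colMeans(M$codebook[spot$unit_indices, , drop = FALSE])
  members <- names(M$gene_to_unit)[M$gene_to_unit %in% spot$unit_indices]
  members <- intersect(members, N$gene_ids)
  if (length(members) == 0) {
    warning("spot ", spot$label, " has no member genes")
    spot$member_genes <- data.frame(gene_id = character(0), r = numeric(0))
  } else {
    r <- as.vector(stats::cor(t(N$values[match(members, N$gene_ids), ,
                                         drop = FALSE]), profile))
    r[is.na(r)] <- 0      # zero-variance gene rows
    ord <- order(r, decreasing = TRUE)
    spot$member_genes <- data.frame(gene_id = members[ord], r = r[ord],
                                    stringsAsFactors = FALSE)
  }
  spot$profile <- stats::setNames(profile, M$cell_ids)
  spot
}

#' Per-cell over-expression spot counts
#'
#' A spot is "on" in a cell when the mean of the cell's portrait over
#' the spot's units strictly exceeds the `cell_threshold_quantile` of
#' that cell's own portrait values — i.e. the spot region belongs to the
#' cell's personal top tail. Counting "on" spots per cell reproduces the
#' spot-number distribution used to contrast cell groups.
#'
#' @param M A `som_model`.
#' @param spots List of `spot_module`s.
#' @param cell_threshold_quantile Per-cell quantile (default 0.90).
#' @return A data.frame (`cell_id`, `n_spots`) plus attribute `on`, the
#'   logical cells x spots indicator matrix.
#' @export
spots_per_cell <- function(M, spots, cell_threshold_quantile = 0.90) {
  stopifnot(inherits(M, "som_model"))
  if (length(spots) < 1) stop("need at least one spot")
  on <- matrix(FALSE, length(M$cell_ids), length(spots),
               dimnames = list(M$cell_ids,
                               vapply(spots, `[[`, character(1), "label")))
  thr <- apply(M$codebook, 2, stats::quantile,
               probs = cell_threshold_quantile, names = FALSE)
  for (s in seq_along(spots)) {
    m <- colMeans(M$codebook[spots[[s]]$unit_indices, , drop = FALSE])
    on[, s] <- m > thr
  }
  out <- data.frame(cell_id = M$cell_ids, n_spots = as.integer(rowSums(on)),
                    stringsAsFactors = FALSE)
  attr(out, "on") <- on
  out
}

#' Split spots whose genes form uncorrelated blocks
#'
#' A detected spot can cover two genuinely distinct modules when their
#' genes were placed on adjacent or shared map units (small modules in
#' particular). This refinement clusters each spot's member genes
#' (average linkage on 1 - Pearson r between gene profiles) into two
#' candidate blocks and splits the spot when the blocks are essentially
#' uncorrelated — mean between-block correlation below `max_between_r` —
#' and both are at least `min_genes` large. A coherent module never
#' splits: any 2-partition of co-regulated genes keeps a high
#' between-block correlation. Split children share the parent's
#' territory gene-wise (units are divided by majority membership, so a
#' child's units need not stay contiguous); labels are reassigned by
#' peak value afterwards.
#'
#' @param spots List of `spot_module`s with member genes attached.
#' @param N The `normalized_matrix` the model was trained on.
#' @param M The `som_model`.
#' @param min_genes Minimum genes per block to allow a split (default 6).
#' @param max_between_r Maximum mean between-block correlation for a
#'   split (default 0.15).
#' @return List of `spot_module`s (possibly longer than the input),
#'   relabelled A, B, C, ... by decreasing peak value.
#' @export
refine_spots <- function(spots, N, M, min_genes = 6, max_between_r = 0.15) {
  out <- list()
  for (sp in spots) {
    genes <- sp$member_genes$gene_id
    if (length(genes) < 2 * min_genes) { out <- c(out, list(sp)); next }
    r <- stats::cor(t(N$values[match(genes, N$gene_ids), , drop = FALSE]))
    r[is.na(r)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    cl <- stats::cutree(hc, k = 2)
    between <- mean(r[cl == 1, cl == 2])
    if (min(table(cl)) < min_genes || between >= max_between_r) {
      out <- c(out, list(sp)); next
    }
    for (k in 1:2) {
      child_genes <- genes[cl == k]
      bmus <- M$gene_to_unit[child_genes]
      units <- sort(unique(bmus))
      # shared units go to the child with more genes there
      other <- M$gene_to_unit[genes[cl != k]]
      shared <- intersect(units, unique(other))
      keep <- vapply(shared, function(u)
        sum(bmus == u) >= sum(other == u), logical(1))
      units <- setdiff(units, shared[!keep])
      if (length(units) == 0) units <- sort(unique(bmus))
      child <- sp
      child$unit_indices <- units
      child$unit_coords <- M$unit_coords[units, , drop = FALSE]
      child$peak_value <- sp$peak_value
      child <- attach_spot_genes(M, N, child)
      out <- c(out, list(child))
    }
  }
  # recompute peaks from profiles and relabel deterministically
  pk <- vapply(out, function(s) max(s$profile), numeric(1))
  out <- out[order(pk, decreasing = TRUE)]
  for (i in seq_along(out)) out[[i]]$label <- make_spot_label(i)
  out
}

#' Find the spot best covering a gene set
#'
#' Returns the spot whose member genes have the largest Jaccard overlap
#' with the given set — e.g. to identify which detected spot recovered a
#' known signature.
#'
#' @param spots List of `spot_module`s with member genes attached.
#' @param set A `gene_set` or character vector of gene ids.
#' @return The best-matching `spot_module` (or `NULL` for an empty spot
#'   list).
#' @export
best_spot_for_set <- function(spots, set) {
  if (length(spots) == 0) return(NULL)
  ids <- if (inherits(set, "gene_set")) set$gene_ids else as.character(set)
  jac <- vapply(spots, function(sp) {
    g <- sp$member_genes$gene_id
    length(intersect(g, ids)) / length(union(g, ids))
  }, numeric(1))
  spots[[which.max(jac)]]
}

#' Match detected spots to reference gene sets
#'
#' For each reference set, finds the spot with the largest overlap
#' between the spot's member genes and the set (Jaccard on memberships).
#' Used to identify which planted program a spot recovered.
#'
#' @param spots List of `spot_module`s with member genes attached.
#' @param sets Named list of character vectors (or `gene_set` objects).
#' @return data.frame: `set`, `spot`, `overlap`, `jaccard`.
#' @export
match_spots_to_sets <- function(spots, sets) {
  sets <- lapply(sets, function(s) if (inherits(s, "gene_set")) s$gene_ids else s)
  rows <- lapply(names(sets), function(nm) {
    ov <- vapply(spots, function(sp)
      length(intersect(sp$member_genes$gene_id, sets[[nm]])), integer(1))
    jac <- vapply(seq_along(spots), function(i)
      ov[i] / length(union(spots[[i]]$member_genes$gene_id, sets[[nm]])),
      numeric(1))
    best <- which.max(jac)
    data.frame(set = nm, spot = spots[[best]]$label,
               overlap = ov[best], jaccard = jac[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
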