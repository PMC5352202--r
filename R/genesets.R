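#' Construct a gene set
#' @param name Set name.
#' @param gene_ids Character vector of member ids (deduplicated).
#' @param description Optional free-text description.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, gene_ids, description = "") {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, gene_ids = gene_ids,
                 description = description), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a line
#' are collapsed; a line without members is a parse error.
#'
#' @param path Path to the GMT file.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("parse error in ", path, " line ", i,
           ": expected name, description and >= 1 member")
    }
    sets[[parts[1]]] <- gene_set(parts[1], parts[-(1:2)], parts[2])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets List of `gene_set` objects (or named list of id vectors).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!inherits(s, "gene_set")) s <- gene_set(names(sets)[i], s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher's exact over-representation test of a spot gene list
#'
#' Classic 2x2 over-representation test on a fixed gene universe:
#' a = |spot intersect set|, b = |spot \ set|, c = |set \ spot|, d = the
#' rest. The p-value is the right-tail hypergeometric probability
#' P(X >= a) of drawing at least `a` set genes when sampling |spot|
#' genes from the universe; the odds ratio is (a d)/(b c) with a 0.5
#' continuity correction applied to all cells whenever any cell is 0.
#'
#' @param spot_members Character vector of spot member gene ids (must be
#'   contained in `universe`).
#' @param set A `gene_set` (intersected with the universe before
#'   testing).
#' @param universe Character vector: all genes the analysis could have
#'   selected (the genes surviving preprocessing).
#' @return An `enrichment_result`: `set`, `a`, `b`, `c`, `d`, `p`,
#'   `odds_ratio`.
#' @export
fisher_enrichment <- function(spot_members, set, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(as.character(universe))
  spot_members <- unique(as.character(spot_members))
  if (length(setdiff(spot_members, universe)) > 0) {
    stop("spot members outside the universe")
  }
  ids <- if (inherits(set, "gene_set")) set$gene_ids else as.character(set)
  ids <- intersect(ids, universe)
  a <- length(intersect(spot_members, ids))
  b <- length(spot_members) - a
  cc <- length(ids) - a
  d <- length(universe) - a - b - cc
  # right tail includes the observed table: P(X >= a)
  p <- stats::phyper(a - 1, length(ids), length(universe) - length(ids),
                     length(spot_members), lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  structure(list(set = if (inherits(set, "gene_set")) set$name else "set",
                 a = a, b = b, c = cc, d = d,
                 p = min(p, 1),
                 odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3])),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment '%s': a=%d b=%d c=%d d=%d, OR=%.3g, p=%.3g\n",
              x$set, x$a, x$b, x$c, x$d, x$odds_ratio, x$p))
  invisible(x)
}

#' Enrichment of every spot against every gene set
#'
#' Runs [fisher_enrichment()] for all spot/set pairs and reports raw
#' p-values, flagging those below `p_threshold` (default 1e-7, the
#' reporting threshold used for spot-module annotation). Optionally adds
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param spots List of `spot_module`s with member genes attached.
#' @param sets List of `gene_set`s.
#' @param universe Gene universe (all genes surviving preprocessing).
#' @param p_threshold Significance threshold on the raw p (default 1e-7).
#' @param adjust Add a BH-adjusted column (default `FALSE`).
#' @return data.frame: `spot`, `set`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `significant` (and `p_adj` when `adjust`).
#' @export
enrich_spots <- function(spots, sets, universe, p_threshold = 1e-7,
                         adjust = FALSE) {
  rows <- list()
  for (sp in spots) for (s in sets) {
    e <- fisher_enrichment(sp$member_genes$gene_id, s, universe)
    rows[[length(rows) + 1]] <- data.frame(
      spot = sp$label, set = e$set, a = e$a, b = e$b, c = e$c, d = e$d,
      odds_ratio = e$odds_ratio, p = e$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_threshold
  out[order(out$spot, out$p), ]
}

#' Per-cell gene set Z-score (GSZ) profile
#'
#' A variance-shrunken standardized set sum: for cell c and the n set
#' genes present in the matrix,
#' `GSZ_c = sum_g e_gc / sqrt(n * sigma2_c)` with
#' `sigma2_c = (n * Var_genes(e_.c) + lambda * Var_global) / (n + lambda)`,
#' where `Var_genes(e_.c)` is the variance over all genes within cell c
#' and `Var_global` the variance of the whole matrix. The shrinkage
#' (`lambda_shrink`, default 10) stabilises the per-cell variance for
#' small sets. Positive scores mean the set is concertedly over-expressed
#' in that cell.
#'
#' @param N A `normalized_matrix`.
#' @param set A `gene_set` (or character vector of ids).
#' @param lambda_shrink Shrinkage weight toward the global variance.
#' @return A `gsz_profile`: `set`, `scores` (named per-cell numeric),
#'   `n_genes_used`, `missing_genes`.
#' @export
gsz_profile <- function(N, set, lambda_shrink = 10) {
  stopifnot(inherits(N, "normalized_matrix"))
  ids <- if (inherits(set, "gene_set")) set$gene_ids else unique(as.character(set))
  nm <- if (inherits(set, "gene_set")) set$name else "set"
  present <- intersect(ids, N$gene_ids)
  if (length(present) == 0) {
    stop("no gene of set '", nm, "' present in the matrix; missing: ",
         paste(utils::head(ids, 10), collapse = ", "))
  }
  n <- length(present)
  set_sum <- colSums(N$values[match(present, N$gene_ids), , drop = FALSE])
  var_cell <- apply(N$values, 2, stats::var)
  var_global <- stats::var(as.vector(N$values))
  sigma2 <- (n * var_cell + lambda_shrink * var_global) / (n + lambda_shrink)
  scores <- set_sum / sqrt(n * sigma2)
  structure(list(set = nm,
                 scores = stats::setNames(scores, N$cell_ids),
                 n_genes_used = n,
                 missing_genes = setdiff(ids, present)),
            class = "gsz_profile")
}

#' @export
print.gsz_profile <- function(x, ...) {
  cat(sprintf("gsz_profile '%s': %d genes, %d cells, score range [%.2f, %.2f]\n",
              x$set, x$n_genes_used, length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Flag cells activating a gene set by its GSZ profile
#'
#' Detects the high-score subpopulation with a largest-gap rule: the
#' scores are sorted and the biggest jump between consecutive values in
#' the upper tail (cells that would flag between `min_fraction` and
#' `max_fraction` of the population) is taken as the threshold. If no
#' jump in that tail stands out against the bulk spacing (gap less than
#' `min_gap_mads` median absolute deviations of the scores), no cell is
#' flagged — the profile is then considered unimodal.
#'
#' @param gsz A `gsz_profile` (or bare numeric vector of scores).
#' @param min_fraction,max_fraction Bounds on the flagged fraction
#'   searched (defaults 0.01 and 0.5).
#' @param min_gap_mads Minimum gap size in MAD units (default 2).
#' @return Logical vector (named by cell) — `TRUE` for flagged cells;
#'   attribute `threshold` carries the cut point (`NA` if none).
#' @export
flag_cells_by_gsz <- function(gsz, min_fraction = 0.01, max_fraction = 0.5,
                              min_gap_mads = 2) {
  scores <- if (inherits(gsz, "gsz_profile")) gsz$scores else gsz
  n <- length(scores)
  s <- sort(scores)
  # candidate cut after sorted position i flags n - i cells
  i_lo <- max(1L, n - floor(max_fraction * n))
  i_hi <- n - max(1L, ceiling(min_fraction * n))
  flags <- stats::setNames(rep(FALSE, n), names(scores))
  if (i_hi < i_lo) return(structure(flags, threshold = NA_real_))
  gaps <- s[(i_lo + 1):(i_hi + 1)] - s[i_lo:i_hi]
  scale <- stats::mad(scores)
  if (scale == 0) scale <- stats::sd(scores)
  best <- which.max(gaps)
  if (length(best) == 0 || scale == 0 || gaps[best] < min_gap_mads * scale) {
    return(structure(flags, threshold = NA_real_))
  }
  cut_i <- i_lo + best - 1L
  thr <- (s[cut_i] + s[cut_i + 1]) / 2
  flags[] <- scores > thr
  structure(flags, threshold = thr)
}

#' Map a gene set onto the SOM grid
#'
#' Counts, for every grid unit, how many set genes have that unit as
#' their best-matching unit. The total count equals the number of set
#' genes present in the model.
#'
#' @param M A `som_model`.
#' @param set A `gene_set` (or character vector).
#' @return A `geneset_map`: `set`, `counts` (grid_rows x grid_cols
#'   integer matrix), `n_present`, `missing_genes`.
#' @export
geneset_map <- function(M, set) {
  stopifnot(inherits(M, "som_model"))
  ids <- if (inherits(set, "gene_set")) set$gene_ids else unique(as.character(set))
  nm <- if (inherits(set, "gene_set")) set$name else "set"
  present <- intersect(ids, names(M$gene_to_unit))
  if (length(present) < length(ids)) {
    message(length(ids) - length(present), " set gene(s) absent from the model")
  }
  counts <- tabulate(M$gene_to_unit[present],
                     nbins = M$grid_rows * M$grid_cols)
  m <- matrix(as.integer(counts), M$grid_rows, M$grid_cols, byrow = TRUE)
  structure(list(set = nm, counts = m, n_present = length(present),
                 missing_genes = setdiff(ids, present)),
            class = "geneset_map")
}

#' @export
print.geneset_map <- function(x, ...) {
  cat(sprintf("geneset_map '%s': %d genes mapped on %d x %d grid\n",
              x$set, x$n_present, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
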