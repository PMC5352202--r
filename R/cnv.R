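#' Infer copy-number variation from expression
#'
#' Estimates large-scale relative copy number by smoothing expression
#' along the genome: (i) `log2(FPKM + 1)`; (ii) per-gene centering
#' across cells; (iii) clipping to `±clip`; (iv) ordering genes by
#' (chromosome, start); (v) per-chromosome moving average over `window`
#' consecutive genes (sliding step 1, or non-overlapping blocks in
#' `"block"` mode); (vi) per-cell median re-centering across all
#' windows. Windows never span two chromosomes. Genes without annotation
#' are dropped with a message. With no normal reference cells available,
#' the per-cell median acts as the neutral baseline, so only events not
#' shared by (essentially) all cells are visible.
#'
#' @param E An [expression_matrix()] (FPKM scale).
#' @param A Annotation data.frame (`gene_id`, `chromosome`, `start`),
#'   e.g. from [read_annotation()].
#' @param window Genes per window (default 50).
#' @param clip Symmetric clip bound on centered log2 values (default 3).
#' @param mode `"sliding"` (default) or `"block"`.
#' @return A `cnv_matrix`: `values` (cells x windows), `windows`
#'   (data.frame: `chromosome`, `first_gene`, `last_gene`, `start`,
#'   `end`, gene-index bounds), `clip`, `n_dropped_genes`.
#' @export
infer_cnv <- function(E, A, window = 50, clip = 3.0,
                      mode = c("sliding", "block")) {
  stopifnot(inherits(E, "expression_matrix"))
  mode <- match.arg(mode)
  validate_annotation(A)
  ann <- A[A$gene_id %in% E$gene_ids, , drop = FALSE]
  n_dropped <- length(E$gene_ids) - nrow(ann)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) without annotation dropped from CNV inference")
  }
  ann <- ann[order(ann$chromosome, ann$start, ann$gene_id), , drop = FALSE]
  if (max(table(ann$chromosome)) < window) {
    stop("no chromosome reaches ", window,
         " annotated genes; use a smaller window")
  }
  x <- log2(E$values[ann$gene_id, , drop = FALSE] + 1)
  x <- x - rowMeans(x)
  x <- pmin(pmax(x, -clip), clip)

  vals <- list(); winfo <- list()
  for (chr in unique(ann$chromosome)) {
    gi <- which(ann$chromosome == chr)
    if (length(gi) < window) next
    xc <- x[gi, , drop = FALSE]                  # genes x cells, ordered
    if (mode == "sliding") {
      sm <- zoo::rollmean(xc, k = window, align = "left")  # windows x cells
      first <- seq_len(length(gi) - window + 1)
    } else {
      nb <- length(gi) %/% window
      first <- (seq_len(nb) - 1) * window + 1
      sm <- t(vapply(first, function(f)
        colMeans(xc[f:(f + window - 1), , drop = FALSE]),
        numeric(ncol(xc))))
    }
    last <- first + window - 1
    vals[[chr]] <- t(sm)                         # cells x windows
    winfo[[chr]] <- data.frame(
      chromosome = chr,
      first_gene = ann$gene_id[gi[first]],
      last_gene = ann$gene_id[gi[last]],
      start = ann$start[gi[first]],
      end = ann$start[gi[last]],
      stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, vals)
  windows <- do.call(rbind, winfo)
  rownames(windows) <- NULL
  values <- values - apply(values, 1, stats::median)
  rownames(values) <- E$cell_ids
  structure(list(values = values, windows = windows, clip = clip,
                 window = window, mode = mode,
                 n_dropped_genes = n_dropped),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("cnv_matrix: %d cells x %d windows (%d-gene %s windows, clip ±%g) over %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), x$window, x$mode, x$clip,
              length(unique(x$windows$chromosome))))
  invisible(x)
}

#' Mean CNV signal per chromosome
#'
#' Averages the windowed CNV values per chromosome, either over all
#' cells or a supplied subset (e.g. event-carrier cells).
#'
#' @param cnv A `cnv_matrix`.
#' @param cell_ids Optional subset of cells.
#' @return data.frame (`chromosome`, `mean_cnv`) sorted by decreasing
#'   signal.
#' @export
cnv_chromosome_summary <- function(cnv, cell_ids = NULL) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  v <- cnv$values
  if (!is.null(cell_ids)) v <- v[cell_ids, , drop = FALSE]
  m <- tapply(colMeans(v), cnv$windows$chromosome, mean)
  out <- data.frame(chromosome = names(m), mean_cnv = as.numeric(m),
                    stringsAsFactors = FALSE)
  out[order(out$mean_cnv, decreasing = TRUE), ]
}

#' Export a CNV matrix and its window annotation
#'
#' Writes `<prefix>_cnv.tsv` (cells x windows) and a BED-like
#' `<prefix>_windows.tsv`.
#'
#' @param cnv A `cnv_matrix`.
#' @param prefix Output path prefix.
#' @export
write_cnv_tsv <- function(cnv, prefix) {
  df <- data.frame(cell_id = rownames(cnv$values), cnv$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, paste0(prefix, "_cnv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cnv$windows, paste0(prefix, "_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
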