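#' Construct an expression matrix container
#'
#' Bundles a nonnegative gene-by-cell expression matrix (FPKM scale) with
#' its gene and cell identifiers and validates the basic invariants every
#' downstream stage relies on: unique ids, finite nonnegative values, and
#' matching dimensions.
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_ids`, `cell_ids`. `values` carries the ids as dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (supply them or use dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) != nrow(values)")
  }
  if (length(cell_ids) != ncol(values)) {
    stop("length(cell_ids) != ncol(values)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be >= 0")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (FPKM scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene-by-cell expression matrix
#'
#' Supports two plain-text layouts: a dense TSV (first column gene id,
#' header row of cell ids) and a MatrixMarket coordinate file accompanied
#' by one-id-per-line row and column sidecar files (`<path>.rownames` /
#' `<path>.colnames` unless given explicitly). Zeros are preserved and
#' values are not transformed in any way.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"` or `"mtx-triplet"`.
#' @param row_names,col_names Sidecar paths for `mtx-triplet`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx-triplet"),
                            row_names = paste0(path, ".rownames"),
                            col_names = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(tab) < 2) stop("parse error in ", path, ": need >= 2 columns")
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1] + 1L
      stop("parse error in ", path, ": non-numeric column ", bad)
    }
    expression_matrix(vals, gene_ids, colnames(tab)[-1])
  } else {
    for (f in c(row_names, col_names)) {
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    }
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    gid <- readLines(row_names)
    cid <- readLines(col_names)
    if (length(gid) != nrow(m) || length(cid) != ncol(m)) {
      stop("sidecar id counts (", length(gid), " x ", length(cid),
           ") do not match declared matrix shape (", nrow(m), " x ",
           ncol(m), ")")
    }
    expression_matrix(as.matrix(m), gid, cid)
  }
}

#' Write an expression matrix as dense TSV
#'
#' @param E An [expression_matrix()] (or `normalized_matrix`).
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_expression_tsv <- function(E, path, id_col = "gene_id") {
  df <- data.frame(E$gene_ids, E$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, E$cell_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with at least three columns: gene id, chromosome, and
#' 0-based start position in base pairs. Extra columns are ignored.
#'
#' @param path Path to the annotation TSV (header required).
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("annotation needs >= 3 columns in ", path)
  ann <- data.frame(gene_id = as.character(tab[[1]]),
                    chromosome = as.character(tab[[2]]),
                    start = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(utils::head(unique(ann$gene_id[duplicated(ann$gene_id)]), 5),
               collapse = ", "))
  }
  if (any(!is.finite(ann$start))) stop("annotation starts must be finite")
  if (any(ann$start < 0)) stop("annotation starts must be >= 0")
  if (any(!nzchar(ann$chromosome))) stop("empty chromosome name in annotation")
  invisible(ann)
}
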