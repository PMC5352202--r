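#' Assemble a pipeline run configuration
#'
#' Flat key-value configuration covering every stage of the portrayal
#' pipeline, with the module defaults filled in. Unknown keys are
#' rejected. A configuration round-trips through JSON
#' ([read_run_config()] / [write_run_config()]).
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `run_config` list with keys: `matrix_path`,
#'   `annotation_path`, `gmt_path`, `out_dir` (all optional paths),
#'   `housekeeping`, `log_transform`, `min_sd`, `som_rows`, `som_cols`
#'   (`NA` = choose from gene count, about 5 genes per metagene capped
#'   at 50 x 50), `epochs`, `summary_quantile`, `spot_threshold_quantile`,
#'   `spot_min_units`, `spot_method`, `spot_tolerance`,
#'   `cell_threshold_quantile`, `k`, `k_range`,
#'   `linkage`, `edge_threshold`, `lambda_shrink`, `p_threshold`,
#'   `cnv_window`, `cnv_clip`, `cnv_mode`, `seed`.
#' @export
run_config <- function(...) {
  defaults <- list(
    matrix_path = NULL, annotation_path = NULL, gmt_path = NULL,
    out_dir = NULL,
    housekeeping = c("ACTB", "GAPDH"),
    log_transform = TRUE, min_sd = 0,
    som_rows = NA, som_cols = NA, epochs = 30,
    summary_quantile = 0.98,
    spot_threshold_quantile = 0.90, spot_min_units = 5,
    spot_method = "components", spot_tolerance = 0.15,
    spot_refine = TRUE,
    cell_threshold_quantile = 0.90,
    k = "auto", k_range = 2:8, linkage = "average",
    edge_threshold = 0.3,
    lambda_shrink = 10, p_threshold = 1e-7,
    cnv_window = 50, cnv_clip = 3.0, cnv_mode = "sliding",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$k) && vals$k != "auto") vals$k <- as.integer(vals$k)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration used for the preset culture analyses
#'
#' The settings the bundled culture analyses run with: a 25 x 25 map
#' (about 3 genes per metagene at the default 2,000-gene scale, enough
#' resolution for rare-subpopulation modules), watershed spot
#' segmentation at foreground quantile 0.70 with prominence tolerance
#' 0.03 (log10 expression units) so that adjacent modules with distinct
#' peaks are kept apart, and otherwise the package defaults.
#'
#' @param seed Seed for the run (defaults to the preset seed convention).
#' @param ... Further [run_config()] overrides.
#' @return A [run_config()].
#' @export
preset_run_config <- function(seed = 101, ...) {
  run_config(som_rows = 25, som_cols = 25,
             spot_threshold_quantile = 0.70,
             spot_method = "watershed", spot_tolerance = 0.03,
             seed = seed, ...)
}

auto_grid_dim <- function(n_genes) {
  min(50L, max(10L, as.integer(floor(sqrt(n_genes / 5)))))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full portrayal pipeline
#'
#' Executes preprocess -> SOM -> spots -> groups -> gene sets -> CNV in
#' order: housekeeping QC, quantile normalization + centralization,
#' invariant-gene removal, SOM training, summary over-expression map and
#' spot segmentation with gene ranking, per-cell spot counts, portrait
#' correlation clustering with silhouette-selected k, similarity
#' network, per-spot Fisher enrichment and per-set GSZ profiles (when
#' gene sets are given), and expression-inferred CNV (when annotation is
#' given). Identical configuration and seed reproduce the run bit for
#' bit. A stage failure aborts with the stage named; when an output
#' directory is set, everything computed up to the failure is already on
#' disk.
#'
#' @param cfg A [run_config()].
#' @param matrix An [expression_matrix()]; defaults to reading
#'   `cfg$matrix_path`.
#' @param annotation Optional annotation data.frame (or
#'   `cfg$annotation_path`).
#' @param gene_sets Optional list of `gene_set`s (or `cfg$gmt_path`).
#' @return A `run_report` list: `qc`, `n_genes_used`, `som` (model),
#'   `spots`, `spot_counts`, `correlations`, `grouping`, `network`,
#'   `group_table` (sizes and percentages), `enrichment`, `gsz`, `cnv`,
#'   `config`, `config_hash`, `version`.
#' @export
run_pipeline <- function(cfg = run_config(), matrix = NULL,
                         annotation = NULL, gene_sets = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  persist <- function(f, ...) if (!is.null(out)) f(...)

  E <- stage("input", {
    if (is.null(matrix)) {
      if (is.null(cfg$matrix_path)) stop("no matrix or matrix_path given")
      read_expression(cfg$matrix_path)
    } else matrix
  })
  if (is.null(annotation) && !is.null(cfg$annotation_path)) {
    annotation <- stage("input", read_annotation(cfg$annotation_path))
  }
  if (is.null(gene_sets) && !is.null(cfg$gmt_path)) {
    gene_sets <- stage("genesets", read_gmt(cfg$gmt_path))
  }

  qc <- stage("qc", qc_filter_cells(E, cfg$housekeeping))
  N <- stage("normalize", {
    n <- normalize_expression(qc$matrix, log_transform = cfg$log_transform)
    filter_invariant_genes(n, min_sd = cfg$min_sd)
  })
  persist(write_expression_tsv, N, file.path(out, "normalized.tsv"))

  rows <- if (is.na(cfg$som_rows)) auto_grid_dim(nrow(N$values)) else cfg$som_rows
  cols <- if (is.na(cfg$som_cols)) rows else cfg$som_cols
  M <- stage("som", train_som(N, grid_rows = rows, grid_cols = cols,
                              epochs = cfg$epochs, seed = cfg$seed))
  persist(write_som_model, M, file.path(out, "som"))

  spots <- stage("spots", {
    smap <- summary_overexpression_map(M, q = cfg$summary_quantile)
    sp <- detect_spots(smap, threshold_quantile = cfg$spot_threshold_quantile,
                       min_units = cfg$spot_min_units,
                       method = cfg$spot_method,
                       tolerance = cfg$spot_tolerance)
    sp <- lapply(sp, function(s) attach_spot_genes(M, N, s))
    if (isTRUE(cfg$spot_refine) && length(sp)) {
      sp <- refine_spots(sp, N, M)
    }
    sp
  })
  spot_counts <- if (length(spots)) {
    stage("spots", spots_per_cell(M, spots, cfg$cell_threshold_quantile))
  } else NULL
  persist(write_spots_json, spots, file.path(out, "spots.json"))

  C <- stage("groups", portrait_correlations(M))
  grouping <- stage("groups", cluster_cells(C, k = cfg$k,
                                            k_range = cfg$k_range,
                                            linkage = cfg$linkage))
  network <- stage("groups", build_network(C, cfg$edge_threshold, grouping))
  persist(write_grouping_tsv, grouping, file.path(out, "groups.tsv"))

  sizes <- table(grouping$assignment)
  group_table <- data.frame(group = as.integer(names(sizes)),
                            n_cells = as.integer(sizes),
                            percent = round(100 * as.integer(sizes) /
                                              sum(sizes), 1))

  enrichment <- NULL; gsz <- NULL
  if (!is.null(gene_sets) && length(spots)) {
    enrichment <- stage("genesets",
      enrich_spots(spots, gene_sets, universe = N$gene_ids,
                   p_threshold = cfg$p_threshold))
    gsz <- stage("genesets", lapply(gene_sets, function(s)
      gsz_profile(N, s, lambda_shrink = cfg$lambda_shrink)))
    persist(utils::write.table, enrichment,
            file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
  }

  cnv <- NULL
  if (!is.null(annotation)) {
    cnv <- stage("cnv", infer_cnv(qc$matrix, annotation,
                                  window = cfg$cnv_window,
                                  clip = cfg$cnv_clip,
                                  mode = cfg$cnv_mode))
    persist(write_cnv_tsv, cnv, file.path(out, "inferred"))
  }

  report <- structure(list(
    qc = qc$report,
    n_genes_used = nrow(N$values),
    normalized = N,
    som = M,
    spots = spots,
    spot_counts = spot_counts,
    correlations = C,
    grouping = grouping,
    network = network,
    group_table = group_table,
    enrichment = enrichment,
    gsz = gsz,
    cnv = cnv,
    config = cfg,
    config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("somcell"))
  ), class = "run_report")
  persist(write_run_summary, report, file.path(out, "report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  print(x$qc)
  cat(sprintf("  %d genes used, %d x %d map\n", x$n_genes_used,
              x$som$grid_rows, x$som$grid_cols))
  cat(sprintf("  %d spots (%s), %d groups (%s%% of cells)\n",
              length(x$spots),
              paste(vapply(x$spots, `[[`, character(1), "label"),
                    collapse = ""),
              x$grouping$k, paste(x$group_table$percent, collapse = "/")))
  invisible(x)
}

write_spots_json <- function(spots, path) {
  jsonlite::write_json(lapply(spots, function(s) list(
    label = s$label,
    units = s$unit_coords,
    peak_value = s$peak_value,
    profile = s$profile,
    top_genes = utils::head(s$member_genes, 10))), path, digits = NA)
  invisible(path)
}

write_run_summary <- function(report, path) {
  jsonlite::write_json(list(
    n_input_cells = report$qc$n_input_cells,
    n_retained = report$qc$n_retained,
    n_genes_used = report$n_genes_used,
    grid = c(report$som$grid_rows, report$som$grid_cols),
    k = report$grouping$k,
    group_table = report$group_table,
    spots = vapply(report$spots, `[[`, character(1), "label"),
    overall_silhouette = report$grouping$overall_silhouette,
    config_hash = report$config_hash,
    version = report$version), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Percentage of cells in the group owning a program's spot
#'
#' Identifies the spot most enriched for the given gene set (smallest
#' right-tail Fisher p over the run's spots), attributes it to the cell
#' group whose portraits peak there, and returns that group's share of
#' cells — e.g. the proliferative-group percentage via a cell-cycle
#' signature.
#'
#' @param report A `run_report`.
#' @param set A `gene_set` (or character vector of gene ids).
#' @return Percentage of cells (0-100); attribute `group` carries the
#'   group index, attribute `spot` the spot label.
#' @export
program_group_percent <- function(report, set) {
  stopifnot(inherits(report, "run_report"))
  if (length(report$spots) == 0) stop("run has no spots")
  p <- vapply(report$spots, function(sp)
    fisher_enrichment(sp$member_genes$gene_id, set,
                      report$normalized$gene_ids)$p, numeric(1))
  spot <- report$spots[[which.min(p)]]
  grp <- group_for_spot(report$som, report$grouping, spot)
  pct <- 100 * mean(report$grouping$assignment == grp)
  structure(pct, group = grp, spot = spot$label)
}

#' Fraction of cells flagged by a spot's GSZ profile
#'
#' Takes the spot best covering the given gene set, computes the GSZ
#' profile of the spot's member genes, and flags the high-score
#' subpopulation with the largest-gap rule of [flag_cells_by_gsz()] —
#' the detection rule for rare subpopulations such as drug-resistance
#' marker modules.
#'
#' @param report A `run_report`.
#' @param set A `gene_set` or id vector locating the spot of interest.
#' @return Fraction of cells flagged (0-1); attribute `spot` carries
#'   the spot label used.
#' @export
spot_gsz_flag_fraction <- function(report, set) {
  stopifnot(inherits(report, "run_report"))
  spot <- best_spot_for_set(report$spots, set)
  if (is.null(spot)) stop("run has no spots")
  g <- gsz_profile(report$normalized,
                   gene_set(paste0("spot_", spot$label),
                            spot$member_genes$gene_id))
  structure(mean(flag_cells_by_gsz(g)), spot = spot$label)
}

#' Joint portrayal of several cultures
#'
#' Concatenates the cells of two or more expression matrices on their
#' common genes, tags every cell with its culture of origin, retrains
#' the map on the union (so shared programs land on shared spots), and
#' augments the report with per-culture spot activity: for every spot,
#' the fraction of each culture's cells in which the spot is "on".
#'
#' @param matrices Named list of [expression_matrix()] objects (>= 2).
#' @param cfg A [run_config()].
#' @return A `run_report` with extra fields `culture` (named vector,
#'   cell -> culture) and `spot_activity` (data.frame: spot x culture
#'   fraction of cells with the spot on).
#' @export
joint_analysis <- function(matrices, cfg = run_config()) {
  if (length(matrices) < 2) stop("need >= 2 matrices")
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    names(matrices) <- paste0("culture", seq_along(matrices))
  }
  common <- Reduce(intersect, lapply(matrices, `[[`, "gene_ids"))
  if (length(common) < 100) {
    stop("gene intersection too small (", length(common), " < 100)")
  }
  culture <- character(0)
  cols <- list()
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    v <- m$values[common, , drop = FALSE]
    colnames(v) <- paste(nm, m$cell_ids, sep = ":")
    cols[[nm]] <- v
    culture <- c(culture, stats::setNames(rep(nm, ncol(v)), colnames(v)))
  }
  E <- expression_matrix(do.call(cbind, cols))
  report <- run_pipeline(cfg, matrix = E)
  report$culture <- culture[report$som$cell_ids]
  if (length(report$spots)) {
    on <- attr(report$spot_counts, "on")
    acts <- lapply(unique(report$culture), function(cu) {
      colMeans(on[report$culture == cu, , drop = FALSE])
    })
    report$spot_activity <- data.frame(
      spot = colnames(on),
      do.call(cbind, stats::setNames(acts, unique(report$culture))),
      check.names = FALSE, row.names = NULL)
  }
  report
}
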