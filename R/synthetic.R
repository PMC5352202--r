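#' Specify a planted expression program
#'
#' A program is a set of genes concertedly shifted upward (on the
#' natural-log scale) in its carrier cells. Mutually exclusive major
#' programs define the cell groups; `overlap_with` lets a program also
#' fire, at `overlap_effect` times its effect, in the carrier cells of
#' another program — modelling signatures shared between groups (e.g.
#' an energy-metabolism module up in two groups at different strength).
#'
#' @param name Program name.
#' @param n_genes Number of marker genes.
#' @param cell_fraction Fraction of retained cells carrying the program
#'   (ignored when `carrier_program` is set — the carrier set is then
#'   inherited).
#' @param effect Log-scale (natural log) mean shift in carriers
#'   (default 2).
#' @param carrier_program Optional name of a major program whose cell
#'   group this program fires in at full effect (instead of defining its
#'   own group).
#' @param overlap_with Optional name of another major program whose
#'   carrier cells also activate this program.
#' @param overlap_effect Multiplier on `effect` in the `overlap_with`
#'   carriers (default 0.5).
#' @return A `program_spec` list.
#' @export
program_spec <- function(name, n_genes, cell_fraction = NULL, effect = 2.0,
                         carrier_program = NULL, overlap_with = NULL,
                         overlap_effect = 0.5) {
  stopifnot(n_genes >= 1)
  if (is.null(carrier_program)) {
    stopifnot(!is.null(cell_fraction), cell_fraction > 0, cell_fraction <= 1)
  }
  structure(list(name = name, n_genes = as.integer(n_genes),
                 cell_fraction = cell_fraction, effect = effect,
                 carrier_program = carrier_program,
                 overlap_with = overlap_with,
                 overlap_effect = overlap_effect),
            class = "program_spec")
}

is_major_program <- function(p) {
  is.null(p$carrier_program)
}

#' Assemble a synthetic-data configuration
#'
#' Defines a gene-by-cell FPKM matrix with planted structure: mutually
#' exclusive major expression programs partitioning the cells into
#' groups, rare subpopulation programs layered on top, chamber (QC)
#' failures with silenced housekeeping genes, expression-dependent
#' dropout, log-normal library-size variation, and optional chromosomal
#' copy-number events.
#'
#' @param n_genes Total genes (default 2,000; use ~15,000 for
#'   paper-scale runs).
#' @param n_cells Total captured cells including QC failures
#'   (default 96, a full capture chip).
#' @param programs List of mutually exclusive major [program_spec()]s
#'   (fractions summing to <= 1) plus any overlap programs.
#' @param rare_programs List of [program_spec()]s drawn independently of
#'   the major groups (rare subpopulations).
#' @param n_qc_fail Cells with both housekeeping genes forced to 0
#'   (default 4).
#' @param dropout_rate Base dropout probability; an entry with value x
#'   is zeroed with probability `dropout_rate / (1 + x)` (default 0.9,
#'   which leaves roughly 40% of genes detected per cell — the detection
#'   rate typical of microfluidic single-cell FPKM data).
#' @param library_size_sigma SD of the log-normal per-cell library
#'   factor (default 0.3).
#' @param noise_sigma SD of the per-entry log-scale noise (default 0.8).
#' @param mu_mean,mu_sd Mean and SD of the per-gene baseline log
#'   expression (defaults -1 and 2).
#' @param marker_mu_mean,marker_mu_sd Baseline model for planted program
#'   marker genes: half-normal, `marker_mu_mean + |N(0, marker_mu_sd)|`
#'   (defaults 0.5 and 1). Markers sit in the detectable expression
#'   range by construction — a signature gene that is almost never
#'   captured could not have been identified as a marker in the first
#'   place.
#' @param n_chromosomes Chromosomes genes are spread over (default 20).
#' @param group_merge Optional named character vector mapping major
#'   program names to reported group labels (e.g. two cross-activating
#'   programs forming one biological group); defaults to the identity.
#' @param cnv_events List of `list(chromosome=, fraction=, shift=)`
#'   entries: all genes on `chromosome` are multiplied by `2^shift` in
#'   `fraction` of the retained cells.
#' @param seed Integer seed for all cell-level draws (mandatory).
#' @param layout_seed Seed for the genome layout: gene-to-chromosome
#'   placement, program gene membership and per-gene baselines. Shared
#'   across presets by default (7701), so different cultures and
#'   replicates describe the same genes — a signature planted in two
#'   cultures occupies the same gene ids in both.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_cells = 96,
                             programs = list(), rare_programs = list(),
                             n_qc_fail = 4, dropout_rate = 0.9,
                             library_size_sigma = 0.3, noise_sigma = 0.8,
                             mu_mean = -1, mu_sd = 2,
                             marker_mu_mean = 0.5, marker_mu_sd = 1,
                             n_chromosomes = 20, group_merge = NULL,
                             cnv_events = list(), seed,
                             layout_seed = 7701) {
  if (missing(seed)) stop("seed is mandatory")
  major <- Filter(is_major_program, programs)
  fr <- vapply(major, `[[`, numeric(1), "cell_fraction")
  if (sum(fr) > 1 + 1e-9) {
    stop("fractions of mutually exclusive major programs sum to ",
         round(sum(fr), 3), " > 1")
  }
  mnames <- vapply(major, `[[`, character(1), "name")
  for (p in programs) {
    for (ref in c(p$carrier_program, p$overlap_with)) {
      if (!ref %in% mnames)
        stop("program ", p$name, " references unknown major program ", ref)
    }
  }
  for (ev in cnv_events) {
    if (ev$fraction < 0 || ev$fraction > 1)
      stop("cnv event fraction outside [0,1]")
  }
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate outside [0,1]")
  if (n_qc_fail >= n_cells) stop("n_qc_fail must be < n_cells")
  structure(list(n_genes = n_genes, n_cells = n_cells, programs = programs,
                 rare_programs = rare_programs, n_qc_fail = n_qc_fail,
                 dropout_rate = dropout_rate,
                 library_size_sigma = library_size_sigma,
                 noise_sigma = noise_sigma, mu_mean = mu_mean,
                 mu_sd = mu_sd, marker_mu_mean = marker_mu_mean,
                 marker_mu_sd = marker_mu_sd,
                 n_chromosomes = n_chromosomes, group_merge = group_merge,
                 cnv_events = cnv_events, seed = as.integer(seed),
                 layout_seed = as.integer(layout_seed)),
            class = "synthetic_config")
}

# exact integer counts for fractions over n items (largest remainder)
exact_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- round(sum(raw)) - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Draws the matrix described by a [synthetic_config()]:
#' `e_gc = exp(mu_g + shifts + N(0, noise_sigma)) * lib_c`, where shifts
#' collect program effects (natural-log scale) and copy-number events
#' (`shift * log(2)`), `lib_c` is the log-normal library factor, and
#' dropout then zeroes entry `e` with probability
#' `dropout_rate / (1 + e)`. Housekeeping genes ACTB/GAPDH are planted
#' at high baseline expression; the `n_qc_fail` designated failure cells
#' have both forced to 0. All draws come from the seeded generator, so a
#' fixed seed reproduces the output bit for bit.
#'
#' @param config A [synthetic_config()].
#' @return A list:
#'   * `matrix`: the [expression_matrix()] (FPKM scale);
#'   * `annotation`: gene annotation data.frame (`gene_id`,
#'     `chromosome`, `start`);
#'   * `truth`: ground-truth list — `cell_program` (named character,
#'     which major program's cell population each cell belongs to),
#'     `cell_group` (programs collapsed through `group_merge`: the
#'     biological group labels), `rare_flags` (cells x rare programs
#'     logical), `gene_baseline` (the drawn per-gene log means),
#'     `gene_program`
#'     (named character, `"background"` for unplanted genes),
#'     `cnv_carrier` (cells x events logical), `qc_fail_cells`,
#'     `group_of_program` (major program name -> group index);
#'   * `gene_sets`: named list of `gene_set`s (one per program, plus
#'     ABC-like/ALDH-like sublabels when present).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ng <- config$n_genes; nc <- config$n_cells

  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  gene_ids[1:2] <- c("ACTB", "GAPDH")
  cell_ids <- sprintf("cell_%03d", seq_len(nc))

  # --- genome layout block (layout_seed): shared across cultures -----
  set.seed(config$layout_seed)

  # genes spread uniformly over chromosomes, increasing starts
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(config$n_chromosomes)), ng))
  chrom <- chrom[order(as.integer(sub("chr", "", chrom)))]
  gene_order <- sample.int(ng)                  # random genome placement
  annotation <- data.frame(gene_id = gene_ids[gene_order],
                           chromosome = chrom, start = NA_real_,
                           stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    annotation$start[annotation$chromosome == ch] <- (seq_len(k) - 1) * 1e4
  }

  # gene -> program assignment: canonical name-keyed slices of a shared
  # pool, so a program of the same name and size occupies the same gene
  # ids in every culture drawn on this layout (a cross-culture signature
  # really is the same genes); unknown names fall back to the remainder
  # of the pool in listing order
  all_programs <- c(config$programs, config$rare_programs)
  need <- sum(vapply(all_programs, `[[`, integer(1), "n_genes"))
  if (need > ng - 2) stop("programs need more genes than available")
  gene_program <- stats::setNames(rep("background", ng), gene_ids)
  pool <- sample(setdiff(seq_len(ng), 1:2))     # random, non-housekeeping
  registry <- c(proliferation = 150, oxphos = 120, pigmentation = 120,
                stroma = 150, abc_aldh = 24, kdm5b = 20,
                mut_specific = 150, stroma_like = 150)
  reg_start <- stats::setNames(cumsum(c(1, unname(registry)[-length(registry)])),
                               names(registry))
  # canonical slices need room; small toy layouts allocate sequentially
  use_registry <- sum(registry) + need <= length(pool)
  taken <- if (use_registry) sum(registry) else 0
  program_genes <- list()
  for (p in all_programs) {
    if (use_registry && p$name %in% names(registry) &&
        p$n_genes == registry[[p$name]]) {
      idx <- pool[reg_start[[p$name]] + seq_len(p$n_genes) - 1]
    } else {
      if (taken + p$n_genes > length(pool)) stop("programs need more genes than available")
      idx <- pool[(taken + 1):(taken + p$n_genes)]
      taken <- taken + p$n_genes
    }
    program_genes[[p$name]] <- gene_ids[idx]
    gene_program[idx] <- p$name
  }

  # per-gene baseline log expression; markers drawn from the detectable
  # range, housekeepers fixed high
  mu <- stats::rnorm(ng, config$mu_mean, config$mu_sd)
  marker_idx <- which(gene_program != "background")
  mu[marker_idx] <- config$marker_mu_mean +
    abs(stats::rnorm(length(marker_idx), 0, config$marker_mu_sd))
  mu[1:2] <- log(500)

  # --- cell-level block (seed): everything culture-specific ----------
  set.seed(config$seed)

  # QC failures and cell groups (exact counts over retained cells)
  qc_fail <- sort(sample(seq_len(nc), config$n_qc_fail))
  retained <- setdiff(seq_len(nc), qc_fail)
  major <- Filter(is_major_program, config$programs)
  mfr <- vapply(major, `[[`, numeric(1), "cell_fraction")
  mnames <- vapply(major, `[[`, character(1), "name")
  counts <- exact_counts(mfr, length(retained))
  slack <- length(retained) - sum(counts)       # cells outside all programs
  glab <- sample(rep(c(mnames, if (slack > 0) "none"),
                     times = c(counts, if (slack > 0) slack)))
  cell_group <- stats::setNames(rep("none", nc), cell_ids)
  cell_group[retained] <- glab
  # QC-fail chambers hold ordinary cells too: label them by the same law
  if (length(qc_fail) > 0 && length(mnames) > 0) {
    cell_group[qc_fail] <- sample(c(mnames, if (slack > 0) "none"), length(qc_fail),
                                  replace = TRUE,
                                  prob = c(counts, if (slack > 0) slack))
  }

  rare_flags <- matrix(FALSE, nc, length(config$rare_programs),
                       dimnames = list(cell_ids,
                                       vapply(config$rare_programs, `[[`,
                                              character(1), "name")))
  rare_carriers <- list()
  for (p in config$rare_programs) {
    k <- round(p$cell_fraction * length(retained))
    picked <- sample(retained, k)
    rare_carriers[[p$name]] <- sort(picked)
    rare_flags[picked, p$name] <- TRUE
  }

  # log-scale expression model
  L <- matrix(mu, ng, nc) +
    matrix(stats::rnorm(ng * nc, 0, config$noise_sigma), ng, nc)
  for (p in config$programs) {
    gidx <- match(program_genes[[p$name]], gene_ids)
    prim_group <- if (is.null(p$carrier_program)) p$name else p$carrier_program
    prim <- which(cell_group == prim_group)
    L[gidx, prim] <- L[gidx, prim] + p$effect
    if (!is.null(p$overlap_with)) {
      sec <- which(cell_group == p$overlap_with)
      L[gidx, sec] <- L[gidx, sec] + p$effect * p$overlap_effect
    }
  }
  for (p in config$rare_programs) {
    gidx <- match(program_genes[[p$name]], gene_ids)
    L[gidx, rare_carriers[[p$name]]] <- L[gidx, rare_carriers[[p$name]]] + p$effect
  }

  # copy-number events: multiply a whole chromosome in carrier cells
  cnv_carrier <- matrix(FALSE, nc, length(config$cnv_events),
                        dimnames = list(cell_ids,
                                        vapply(config$cnv_events,
                                               function(e) e$chromosome,
                                               character(1))))
  for (i in seq_along(config$cnv_events)) {
    ev <- config$cnv_events[[i]]
    gidx <- match(annotation$gene_id[annotation$chromosome == ev$chromosome],
                  gene_ids)
    picked <- sample(retained, round(ev$fraction * length(retained)))
    cnv_carrier[picked, i] <- TRUE
    L[gidx, picked] <- L[gidx, picked] + ev$shift * log(2)
  }

  lib <- exp(stats::rnorm(nc, 0, config$library_size_sigma))
  X <- exp(L) * rep(lib, each = ng)

  # expression-dependent dropout
  if (config$dropout_rate > 0) {
    pdrop <- config$dropout_rate / (1 + X)
    X[matrix(stats::runif(ng * nc), ng, nc) < pdrop] <- 0
  }
  X[1:2, qc_fail] <- 0                           # chamber failures

  sets <- lapply(names(program_genes), function(nm)
    gene_set(nm, program_genes[[nm]]))
  names(sets) <- names(program_genes)
  # split an ABC/ALDH-style combined rare set into its sublabels
  if ("abc_aldh" %in% names(program_genes)) {
    g <- program_genes[["abc_aldh"]]
    n_abc <- min(16, length(g))
    sets[["abc_like"]] <- gene_set("abc_like", g[seq_len(n_abc)])
    if (length(g) > n_abc) {
      sets[["aldh_like"]] <- gene_set("aldh_like", g[(n_abc + 1):length(g)])
    }
    gene_program[g[seq_len(n_abc)]] <- "abc_like"
    if (length(g) > n_abc) gene_program[g[(n_abc + 1):length(g)]] <- "aldh_like"
  }

  group_of_program <- stats::setNames(seq_along(mnames), mnames)
  merged <- cell_group
  if (!is.null(config$group_merge)) {
    hit <- cell_group %in% names(config$group_merge)
    merged[hit] <- config$group_merge[cell_group[hit]]
  }
  truth <- list(cell_program = cell_group,
                cell_group = merged,
                gene_baseline = stats::setNames(mu, gene_ids),
                rare_flags = rare_flags,
                gene_program = gene_program,
                cnv_carrier = cnv_carrier,
                qc_fail_cells = cell_ids[qc_fail],
                group_of_program = group_of_program)

  list(matrix = expression_matrix(X, gene_ids, cell_ids),
       annotation = annotation,
       truth = truth,
       gene_sets = sets)
}

#' Preset synthetic-culture configurations
#'
#' Ready-made configurations emulating patient-derived melanoma
#' short-term cultures profiled on a 96-chamber capture chip:
#'
#' * `wtwt` — the BRAF/NRAS double wild type culture: three major cell
#'   groups of the 92 retained cells — proliferation 45%, a mixed group
#'   28% whose cells divide into oxphos-dominant and
#'   pigmentation-dominant halves with 0.6 cross-activation, and stroma
#'   27% — plus rare ABC/ALDH (10%, 16 + 8 marker genes) and KDM5B-like
#'   (7%) subpopulations and 4 QC-failing chambers.
#' * `wtwt_replicate` — same culture, independent experiment: differs
#'   only in seed and a 46% proliferative fraction.
#' * `mutwt` — BRAF mutant culture: proliferation 30%, a dominant
#'   culture-specific program, ABC/ALDH at 30%, and subclonal
#'   copy-number gains on chr11, chr8, chr5 and chr19.
#' * `wtmut` — NRAS mutant culture: proliferation 36% with a dominant
#'   stroma-like program and ABC/ALDH at 30%.
#'
#' @param name One of `"wtwt"`, `"wtwt_replicate"`, `"mutwt"`,
#'   `"wtmut"`.
#' @param seed Override the preset's documented default seed.
#' @return A [synthetic_config()].
#' @export
preset <- function(name = c("wtwt", "wtwt_replicate", "mutwt", "wtmut"),
                   seed = NULL) {
  if (!is.character(name) || !name[1] %in%
      c("wtwt", "wtwt_replicate", "mutwt", "wtmut")) {
    stop("unknown preset '", name[1],
         "'; available: wtwt, wtwt_replicate, mutwt, wtmut")
  }
  name <- match.arg(name)
  rare <- list(
    program_spec("abc_aldh", n_genes = 24, cell_fraction = 0.10),
    program_spec("kdm5b", n_genes = 20, cell_fraction = 0.07))
  # The non-proliferative, non-stromal remainder is one biological group
  # whose cells split into an oxphos-dominant and a pigmentation-dominant
  # half; each module also fires at 0.6 strength in the sibling half, so
  # the two spots are distinct on the map while the cells cluster as one
  # group.
  wtwt_programs <- function(prolif_fraction, mixed_fraction) list(
    program_spec("proliferation", 150, prolif_fraction),
    program_spec("oxphos", 120, mixed_fraction / 2,
                 overlap_with = "pigmentation", overlap_effect = 0.6),
    program_spec("pigmentation", 120, mixed_fraction / 2,
                 overlap_with = "oxphos", overlap_effect = 0.6),
    program_spec("stroma", 150, 0.27))
  wtwt_merge <- c(oxphos = "mixed", pigmentation = "mixed")
  cfg <- switch(name,
    wtwt = synthetic_config(
      programs = wtwt_programs(0.45, 0.28), group_merge = wtwt_merge,
      rare_programs = rare, seed = 101),
    wtwt_replicate = synthetic_config(
      programs = wtwt_programs(0.46, 0.27), group_merge = wtwt_merge,
      rare_programs = rare, seed = 102),
    mutwt = synthetic_config(
      n_cells = 58,
      programs = list(
        program_spec("proliferation", 150, 0.30),
        program_spec("mut_specific", 150, 0.70)),
      rare_programs = list(
        program_spec("abc_aldh", n_genes = 24, cell_fraction = 0.30)),
      cnv_events = list(
        list(chromosome = "chr11", fraction = 0.6, shift = 1.0),
        list(chromosome = "chr8", fraction = 0.6, shift = 1.0),
        list(chromosome = "chr5", fraction = 0.6, shift = 1.0),
        list(chromosome = "chr19", fraction = 0.6, shift = 1.0)),
      seed = 103),
    wtmut = synthetic_config(
      n_cells = 81,
      programs = list(
        program_spec("proliferation", 150, 0.36),
        program_spec("stroma_like", 150, 0.64)),
      rare_programs = list(
        program_spec("abc_aldh", n_genes = 24, cell_fraction = 0.30)),
      seed = 104))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
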