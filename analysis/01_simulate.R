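#!/usr/bin/env Rscript
# Draw the four synthetic melanoma short-term-culture data sets (double
# wild type, its replicate, and the two mutant cultures) at their
# default seeds and persist matrices, gene annotation, ground-truth
# labels and truth gene sets under results/simulated/.

suppressMessages(library(somcell))

out_root <- file.path("results", "simulated")
for (name in c("wtwt", "wtwt_replicate", "mutwt", "wtmut")) {
  d <- generate_synthetic(preset(name))
  out <- file.path(out_root, name)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(d$matrix, file.path(out, "expression.tsv"))
  utils::write.table(d$annotation, file.path(out, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(d$gene_sets, file.path(out, "truth_sets.gmt"))
  labels <- data.frame(cell_id = d$matrix$cell_ids,
                       program = d$truth$cell_program,
                       group = d$truth$cell_group,
                       qc_fail = d$matrix$cell_ids %in% d$truth$qc_fail_cells)
  for (rp in colnames(d$truth$rare_flags)) {
    labels[[rp]] <- d$truth$rare_flags[, rp]
  }
  utils::write.table(labels, file.path(out, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d genes x %d cells, %d QC failures, %d program(s)",
                  name, nrow(d$matrix$values), ncol(d$matrix$values),
                  length(d$truth$qc_fail_cells), length(d$gene_sets)))
}
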