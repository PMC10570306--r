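#!/usr/bin/env Rscript
# 02 — Pharmacoscopy: classify cells, gate, QC patients, score drugs.
#
# Reads the single-cell table written by 01, trains the feature-based
# viability/cell-class classifier against the generator's truth labels,
# gates to viable cells, summarizes wells, applies the 0.3% control-HSPC
# QC rule, and scores every patient x drug x readout combination as a
# relative reduction versus matched vehicle controls.

suppressPackageStartupMessages(library(mpnscope))

data_dir <- file.path("results", "data")
cells <- data.table::fread(file.path(data_dir, "cells.tsv"))
clinical <- data.table::fread(file.path(data_dir, "clinical.tsv"))

# classifier: trained on a subsample, applied to all cells
set.seed(2)
train_idx <- sample.int(nrow(cells), min(50000L, nrow(cells)))
clf <- train_cell_classifier(cells[train_idx], seed = 2)
cat(sprintf("classifier: accuracy %.3f, viability accuracy %.3f\n",
            clf$report$accuracy, clf$report$viability_accuracy))

# gate per patient to keep peak memory flat on large screens
n_removed <- 0L
gated <- data.table::rbindlist(lapply(unique(cells$patient_id), function(p) {
  g <- classify_and_gate(cells[patient_id == p], clf)
  n_removed <<- n_removed + attr(g, "n_removed")
  g
}))
cat(sprintf("gated: %d viable cells (%d removed)\n", nrow(gated), n_removed))

summaries <- summarize_wells(gated)
qc <- qc_patients(summaries, min_hspc_fraction = 0.003)
cat(sprintf("QC: %d included, %d excluded\n",
            length(qc$included), length(qc$excluded)))

responses <- score_all_drugs(summaries, patients = qc$included)
summary_tab <- cohort_summary(responses, clinical, stratum_col = "driver")

data.table::fwrite(summaries, file.path("results", "well_summaries.tsv"),
                   sep = "\t")
data.table::fwrite(qc$report, file.path("results", "qc_report.tsv"),
                   sep = "\t")
data.table::fwrite(responses, file.path("results", "drug_responses.tsv"),
                   sep = "\t")
data.table::fwrite(summary_tab, file.path("results", "cohort_summary.tsv"),
                   sep = "\t")

resp_tab <- table(responses$class[responses$readout == "HSPC"])
cat("HSPC response classes:",
    paste(names(resp_tab), resp_tab, collapse = ", "), "\n")
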