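#!/usr/bin/env Rscript
# 03 — Proteotype processing and cohort distances.
#
# Per cell type: outlier report, group-structured missingness filter,
# left-censored minimum imputation, hemoglobin-contamination regression.
# Then Euclidean proteotype distances between subcohort pairs on the
# processed granulocyte matrix.

suppressPackageStartupMessages(library(mpnscope))

data_dir <- file.path("results", "data")
clinical <- data.table::fread(file.path(data_dir, "clinical.tsv"))

cell_types <- c(granulocyte = "proteome_granulocyte.tsv",
                HSPC = "proteome_HSPC.tsv",
                `T-cell` = "proteome_Tcell.tsv")
processed <- list()
for (ct in names(cell_types)) {
  raw <- read_intensity_matrix(file.path(data_dir, cell_types[[ct]]))
  raw <- raw[, clinical$patient_id, drop = FALSE]
  mat <- process_proteome(raw, groups = clinical$group, seed = 3)
  processed[[ct]] <- mat
  write_intensity_matrix(mat,
    file.path("results", sprintf("processed_%s.tsv", gsub("[^A-Za-z0-9]", "", ct))))
  ol <- attr(mat, "outliers")
  cat(sprintf("%s: %d/%d proteins retained, %d imputed values, %d outlier flags\n",
              ct, nrow(mat), nrow(raw), sum(attr(mat, "imputed")),
              sum(ol$flag)))
}

pairs <- list(c("HD", "HD"), c("HD", "ET"), c("HD", "MF"), c("ET", "MF"))
dist_out <- cohort_distances(processed$granulocyte, clinical$cohort, pairs,
                             tests = list(c(2, 1), c(3, 1), c(3, 2)))
data.table::fwrite(dist_out$distances,
                   file.path("results", "cohort_distances.tsv"), sep = "\t")
data.table::fwrite(dist_out$tests,
                   file.path("results", "cohort_distance_tests.tsv"), sep = "\t")
print(aggregate(dist ~ pair, dist_out$distances, median))
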