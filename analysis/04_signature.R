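#!/usr/bin/env Rscript
# 04 — Discriminative protein signature by repeated RFE + MLP.
#
# Repeated stratified 70/20/10 splits; recursive feature elimination to 30
# proteins per run (ridge-multinomial importance over 6 CV folds, 10%
# dropped per step); a small-grid MLP scored once on the untouched test
# split; proteins selected in >= 85% of runs form the signature. The
# workflow uses the scaled-down mode (25 runs, threshold 22) to stay
# laptop-sized; the selection scheme is identical to the full 100-run mode.

suppressPackageStartupMessages(library(mpnscope))

data_dir <- file.path("results", "data")
clinical <- data.table::fread(file.path(data_dir, "clinical.tsv"))
mat <- read_intensity_matrix(file.path("results", "processed_granulocyte.tsv"))
mat <- mat[, clinical$patient_id, drop = FALSE]

sel <- suppressWarnings(
  select_signature(t(mat), clinical$group, n_runs = 25, min_freq = 22,
                   base_seed = 100))

freq_tab <- data.frame(protein = names(sel$frequency),
                       n_selected = sel$frequency,
                       in_signature = names(sel$frequency) %in% sel$signature,
                       row.names = NULL)
data.table::fwrite(freq_tab, file.path("results", "signature_frequency.tsv"),
                   sep = "\t")
data.table::fwrite(sel$scores, file.path("results", "signature_run_scores.tsv"),
                   sep = "\t")
writeLines(sel$signature, file.path("results", "signature_proteins.txt"))

cat(sprintf("signature: %d proteins (threshold %d/%d runs)\n",
            length(sel$signature), 22L, 25L))
print(sel$summary)
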