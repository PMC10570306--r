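#!/usr/bin/env Rscript
# 05 — Proteome-clinical associations, differential tests, enrichment,
# and the association network.
#
# Vectorized per-protein ANOVA of the processed granulocyte proteome
# against clinical factors (with confounders where appropriate),
# MF-vs-HD differential t (volcano table), preranked GSEA of the signed
# significances against the simulated gene sets, and the top-protein /
# enriched-pathway / high-confidence-interaction network.

suppressPackageStartupMessages(library(mpnscope))

data_dir <- file.path("results", "data")
clinical <- data.table::fread(file.path(data_dir, "clinical.tsv"))
mat <- read_intensity_matrix(file.path("results", "processed_granulocyte.tsv"))
mat <- mat[, clinical$patient_id, drop = FALSE]
sets <- read_gmt(file.path(data_dir, "sets.gmt"))
edges <- data.table::fread(file.path(data_dir, "edges.tsv"))

# per-protein ANOVA per clinical factor (age as confounder for cohort)
assoc <- list(
  cohort = protein_factor_anova(mat, factor(clinical$cohort),
                                confounder = clinical$age),
  driver = protein_factor_anova(mat, factor(clinical$driver)),
  vaf = protein_factor_anova(mat, clinical$vaf,
                             confounder = factor(clinical$cohort)))
for (f in names(assoc))
  data.table::fwrite(assoc[[f]],
                     file.path("results", sprintf("anova_%s.tsv", f)),
                     sep = "\t")

# MF vs HD volcano
volcano <- differential_t(mat, clinical$cohort, "MF", "HD")
data.table::fwrite(volcano, file.path("results", "volcano_mf_vs_hd.tsv"),
                   sep = "\t")

# enrichment on the signed significance ranking per factor
enrich <- lapply(assoc, function(a) {
  rk <- stats::setNames(a$sign * -log10(pmax(a$p, 1e-300)), a$protein)
  suppressWarnings(gsea_preranked(rk, sets, n_perm = 1000, seed = 5))
})
for (f in names(enrich))
  data.table::fwrite(enrich[[f]],
                     file.path("results", sprintf("gsea_%s.tsv", f)),
                     sep = "\t")

net <- build_network(assoc, enrich = enrich, edges = as.data.frame(edges))
data.table::fwrite(net$nodes, file.path("results", "network_nodes.tsv"),
                   sep = "\t")
data.table::fwrite(net$edges, file.path("results", "network_edges.tsv"),
                   sep = "\t")
cat(sprintf("network: %d nodes, %d edges\n", nrow(net$nodes), nrow(net$edges)))
cat("top cohort-associated proteins:\n")
print(head(assoc$cohort[order(assoc$cohort$p_adj), ], 5))
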