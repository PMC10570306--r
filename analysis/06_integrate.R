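#!/usr/bin/env Rscript
# 06 — Cross-modality integration.
#
# Joins drug responses, proteotypes and clinical annotations: drug-proteome
# Spearman correlation with enrichment, drug-clinical ANOVA counts,
# responder proteome, the MCM-anchored replicative signature and its drug
# correlates, VAF-protein correlations, and the homozygous-CALR drug
# differentials.

suppressPackageStartupMessages(library(mpnscope))

data_dir <- file.path("results", "data")
clinical <- as.data.frame(data.table::fread(file.path(data_dir, "clinical.tsv")))
responses <- as.data.frame(data.table::fread(file.path("results", "drug_responses.tsv")))
sets <- read_gmt(file.path(data_dir, "sets.gmt"))
mats <- list(
  granulocyte = read_intensity_matrix(file.path("results", "processed_granulocyte.tsv")),
  HSPC = read_intensity_matrix(file.path("results", "processed_HSPC.tsv")),
  `T-cell` = read_intensity_matrix(file.path("results", "processed_Tcell.tsv")))

## drug-proteome correlation + enrichment (HSPC readout vs HSPC proteome)
dpc <- suppressWarnings(
  drug_protein_correlation(responses, mats$HSPC, sets, n_perm = 500, seed = 6))
data.table::fwrite(dpc$enrichment,
                   file.path("results", "drug_proteome_enrichment.tsv"),
                   sep = "\t")
if (!is.null(dpc$counts))
  data.table::fwrite(dpc$counts,
                     file.path("results", "drug_proteome_counts.tsv"),
                     sep = "\t")

## drug-clinical ANOVA counts
dca <- drug_clinical_anova(responses, clinical,
                           factors = c("cohort", "driver", "vaf", "sex",
                                       "treated"))
data.table::fwrite(dca$table, file.path("results", "drug_clinical_anova.tsv"),
                   sep = "\t")
data.table::fwrite(dca$counts,
                   file.path("results", "drug_clinical_counts.tsv"), sep = "\t")

## responder proteome for the planted on-target hit (sm01)
rp <- responder_proteome(responses, mats$HSPC, drugs = "sm01", sets = sets,
                         n_perm = 500, seed = 6)
data.table::fwrite(rp$table, file.path("results", "responder_proteome.tsv"),
                   sep = "\t")
cat(sprintf("sm01 responders: %d patients\n", length(rp$responders)))

## replicative signature, MCM categories, signature-drug correlation
rep_sig <- derive_replicative_signature(mats, k = 50)
writeLines(rep_sig$signature,
           file.path("results", "replicative_signature.txt"))
cats <- categorize_mcm(mats)
data.table::fwrite(cats, file.path("results", "mcm_categories.tsv"), sep = "\t")
scores <- signature_scores(mats$granulocyte, rep_sig$signature)
sdc <- signature_drug_correlation(scores, responses)
data.table::fwrite(sdc, file.path("results", "signature_drug_correlation.tsv"),
                   sep = "\t")

## VAF correlations within each driver stratum
for (drv in c("CALR", "JAK2")) {
  vc <- vaf_correlation(mats$granulocyte, clinical, drv, sets = sets,
                        n_perm = 500, seed = 6)
  data.table::fwrite(vc$table,
                     file.path("results", sprintf("vaf_correlation_%s.tsv", drv)),
                     sep = "\t")
  cat(sprintf("%s: %d proteins at p < 0.01\n", drv, length(vc$significant)))
}

## homozygous-CALR oncogenic drug differentials
diffs <- subgroup_drug_differential(responses, clinical)
data.table::fwrite(diffs, file.path("results", "hom_calr_differentials.tsv"),
                   sep = "\t")
ok <- diffs[!is.na(diffs$delta_vs_het_calr) & !is.na(diffs$delta_vs_jak2), ]
cat("top homozygous-CALR differential drugs:\n")
print(head(ok[order(-ok$delta_vs_het_calr), ], 3))
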