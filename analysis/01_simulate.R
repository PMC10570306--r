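#!/usr/bin/env Rscript
# 01 — Simulate the synthetic MPN study.
#
# One seeded generator call produces every input consumed by the later
# steps: the clinical table, the single-cell pharmacoscopy plates, one
# proteome matrix per cell type, gene sets and a protein-interaction edge
# list, together with a machine-readable description of every planted
# effect (truth.json). Downstream scripts only read the files written here.

suppressPackageStartupMessages(library(mpnscope))

seed <- 1L
out_dir <- file.path("results", "data")

u <- protein_universe(1000)

# planted proteome structure:
#  - three 5-protein discriminative directions (disease-general,
#    MF-specific, CALR-specific) feeding the classifier signature
#  - a VAF-scaled block for the mutation-load correlation analyses
#  - a 50-protein MCM4/MCM7-anchored co-regulated block (replicative
#    activity latent shared across cell types)
#  - hemoglobin contamination loading (red-blood-cell carryover)
blocks <- list(
  effect_block("group_discriminative", u[21:25],
               effects = c(HD = 0, `ET-CALR` = 2, `ET-JAK2` = 2,
                           `MF-CALR` = 2, `MF-JAK2` = 2)),
  effect_block("group_discriminative", u[26:30],
               effects = c(HD = 0, `ET-CALR` = 0, `ET-JAK2` = 0,
                           `MF-CALR` = 2, `MF-JAK2` = 2)),
  effect_block("group_discriminative", u[31:35],
               effects = c(HD = 0, `ET-CALR` = 2, `ET-JAK2` = 0,
                           `MF-CALR` = 2, `MF-JAK2` = 0)),
  effect_block("vaf_scaled", u[41:50], effects = 0.04),
  effect_block("anchor_coregulated", c("MCM4", "MCM7", u[200:247]),
               loading = 1, anchors = c("MCM4", "MCM7")),
  effect_block("contaminant_loading", c("HBA", "HBB", "HBD"), loading = 1),
  effect_block("contaminant_loading", u[100:140],
               loading = seq(0.2, 1.2, length.out = 41)))

# planted pharmacoscopy effects:
#  - sm01 halves viable HSPC survival cohort-wide (the on-target hit)
#  - sm03 depletes the oncogenic-marker-positive population only in
#    homozygous (VAF >= 75) CALR patients
drug_effects <- data.frame(
  drug = c("sm01", "sm03"),
  readout = c("HSPC", "oncogenic"),
  survival = c(0.5, 0.4),
  restrict = c("all", "hom_calr"),
  stringsAsFactors = FALSE)

# workflow problem size: 8 patients per group and 1,000 seeded cells per
# well keep a single-CPU, few-GB run while leaving every analysis powered;
# MF-CALR patients are drawn homozygous at 50% so both CALR zygosity
# groups are populated
config <- sim_config(
  n_per_group = c(HD = 8, `ET-CALR` = 8, `ET-JAK2` = 8,
                  `MF-CALR` = 8, `MF-JAK2` = 8),
  n_proteins = 1000,
  blocks = blocks,
  drug_effects = drug_effects,
  cells_per_well = 1000,
  hspc_range = c(0.02, 0.06),
  homozygous_frac = 0.5)

study <- simulate_study(config, seed, out_dir)
saveRDS(config, file.path(out_dir, "config.rds"))

cat(sprintf("cohort: %d patients, %s\n", nrow(study$clinical),
            paste(names(table(study$clinical$group)),
                  table(study$clinical$group), collapse = " ")))
cat(sprintf("cells: %d rows across %d wells\n", nrow(study$pharmacoscopy$cells),
            nrow(study$pharmacoscopy$layout)))
cat(sprintf("proteomes: %s\n",
            paste(names(study$proteomes$matrices), collapse = ", ")))
cat("wrote", out_dir, "\n")
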