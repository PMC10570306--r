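test_that("stream seeds are deterministic, distinct and in range", {
  s <- vapply(1:9, function(k) stream_seed(42L, k), integer(1))
  expect_identical(s, vapply(1:9, function(k) stream_seed(42L, k), integer(1)))
  expect_equal(length(unique(s)), 9L)
  expect_true(all(s >= 0 & s < 2^31 - 1))
  expect_false(stream_seed(1L, 1L) == stream_seed(2L, 1L))
})

test_that("cohort respects the configured design", {
  cfg <- small_screen_config()
  cl <- simulate_cohort(cfg, 3)
  expect_equal(nrow(cl), sum(cfg$n_per_group))
  expect_equal(as.vector(table(cl$group)[names(cfg$n_per_group)]),
               unname(cfg$n_per_group))
  expect_true(all(cl$vaf[cl$group == "HD"] == 0))
  expect_true(all(cl$driver[cl$cohort == "HD"] == "none"))
  het <- cl$driver != "none" & !cl$homozygous
  expect_true(all(cl$vaf[het] >= 20 & cl$vaf[het] <= 60))
  expect_identical(cl$homozygous, cl$vaf >= 75)
  expect_true(all(cl$patient_id[cl$homozygous] %in%
                    cl$patient_id[cl$group == "MF-CALR"]))
  expect_identical(cl, simulate_cohort(cfg, 3))
  expect_false(identical(cl$vaf, simulate_cohort(cfg, 4)$vaf))
})

test_that("homozygous draws follow the configured binomial rate", {
  cfg <- sim_config(n_per_group = c(HD = 1, `ET-CALR` = 1, `ET-JAK2` = 1,
                                    `MF-CALR` = 20, `MF-JAK2` = 1),
                    homozygous_frac = 0.5)
  counts <- vapply(1:30, function(s) sum(simulate_cohort(cfg, s)$homozygous),
                   numeric(1))
  # mean of 30 Binomial(20, 0.5) draws: sd of the mean ~ 0.41
  expect_gt(mean(counts), 10 - 4 * sqrt(20 * 0.25 / 30))
  expect_lt(mean(counts), 10 + 4 * sqrt(20 * 0.25 / 30))
  cfg0 <- sim_config(homozygous_frac = 0)
  expect_false(any(simulate_cohort(cfg0, 1)$homozygous))
})

test_that("noise-free proteome reproduces the additive model exactly", {
  u <- protein_universe(60)
  blk <- effect_block("group_discriminative", u[10:12],
                      effects = c(HD = 0, `ET-CALR` = 1, `ET-JAK2` = 1,
                                  `MF-CALR` = 3, `MF-JAK2` = 3))
  cfg <- sim_config(n_per_group = c(HD = 2, `ET-CALR` = 2, `ET-JAK2` = 2,
                                    `MF-CALR` = 2, `MF-JAK2` = 2),
                    n_proteins = 60, blocks = list(blk),
                    sigma_resid = 0, detect_quantile = 0, mcar_rate = 0)
  cl <- simulate_cohort(cfg, 5)
  pr <- simulate_proteomes(cl, cfg, 5, cell_types = "granulocyte")
  m <- pr$matrices$granulocyte
  base <- pr$truth$baseline
  expect_false(anyNA(m))
  # unaffected protein: exactly the baseline everywhere
  expect_equal(unname(m["P0020", ]), rep(unname(base["P0020"]), nrow(cl)))
  # block protein: baseline + configured group shift
  shift <- c(HD = 0, `ET-CALR` = 1, `ET-JAK2` = 1, `MF-CALR` = 3,
             `MF-JAK2` = 3)[cl$group]
  expect_equal(unname(m[u[10], ]), unname(base[u[10]] + shift))
})

test_that("vaf-scaled block correlates with VAF as planted", {
  u <- protein_universe(60)
  blk <- effect_block("vaf_scaled", u[20:22], effects = 0.05)
  cfg <- sim_config(n_per_group = c(HD = 4, `ET-CALR` = 12, `ET-JAK2` = 12,
                                    `MF-CALR` = 12, `MF-JAK2` = 12),
                    n_proteins = 60, blocks = list(blk), sigma_resid = 0.2,
                    detect_quantile = 0, mcar_rate = 0)
  cl <- simulate_cohort(cfg, 9)
  pr <- simulate_proteomes(cl, cfg, 9, cell_types = "granulocyte")
  m <- pr$matrices$granulocyte
  mut <- cl$driver != "none"
  # oracle: direct correlation of the generated values with the planted VAF
  expect_gt(cor(m[u[20], mut], cl$vaf[mut]), 0.9)
  expect_lt(abs(cor(m["P0040", mut], cl$vaf[mut])), 0.5)
})

test_that("censoring and MCAR produce the configured missingness", {
  cfg <- sim_config(n_per_group = c(HD = 10, `ET-CALR` = 10, `ET-JAK2` = 10,
                                    `MF-CALR` = 10, `MF-JAK2` = 10),
                    n_proteins = 200, detect_quantile = 0.1, mcar_rate = 0)
  cl <- simulate_cohort(cfg, 2)
  pr <- simulate_proteomes(cl, cfg, 2, cell_types = "granulocyte")
  m <- pr$matrices$granulocyte
  # quantile censoring removes ~10% per protein, always the lowest values
  expect_equal(mean(is.na(m)), 0.1, tolerance = 0.02)
  expect_equal(pr$truth$censored$granulocyte, sum(is.na(m)))
})

test_that("plate layout matches the library design", {
  cfg <- small_screen_config()
  lay <- plate_layout(cfg)
  # small molecules: 2 replicates x 2 concentrations = 4 wells
  expect_equal(sum(lay$drug %in% "sm01"), 4L)
  # biologics: 3 replicates x 3 concentrations = 9 wells
  expect_equal(sum(lay$drug %in% "bio01"), 9L)
  expect_equal(sum(lay$role == "DMSO"), cfg$n_control_wells)
  expect_equal(sum(lay$role == "PBS"), cfg$n_control_wells)
  expect_equal(sum(lay$role == "isotype"), cfg$n_control_wells)
  expect_true(all(lay$n_images == 25L))
  expect_false(any(duplicated(lay$well)))
})

test_that("resolve_drug_effects applies subcohort restrictions", {
  cfg <- small_screen_config(
    drug_effects = data.frame(drug = "sm02", readout = "oncogenic",
                              survival = 0.4, restrict = "mf_calr",
                              stringsAsFactors = FALSE))
  cl <- simulate_cohort(cfg, 8)
  eff <- resolve_drug_effects(cl, cfg)
  hit <- eff$drug == "sm02" & eff$readout == "oncogenic"
  mfc <- cl$patient_id[cl$group == "MF-CALR"]
  expect_true(all(eff$survival[hit & eff$patient_id %in% mfc] == 0.4))
  expect_true(all(eff$survival[hit & !eff$patient_id %in% mfc] == 1))
  expect_true(all(eff$survival[!hit] == 1))
})

test_that("unperturbed drug wells are exchangeable with controls", {
  scr <- small_screen()
  summ <- scr$summ
  p1 <- scr$clinical$patient_id[1]
  # sm02 has no planted effect: its HSPC fractions should match DMSO wells
  x <- summ[summ$patient_id == p1 & !is.na(summ$drug) & summ$drug == "sm02"]$frac_hspc
  y <- summ[summ$patient_id == p1 & summ$role == "DMSO"]$frac_hspc
  expect_gt(suppressWarnings(ks.test(x, y))$p.value, 0.01)
})

test_that("planted HSPC kill depletes the viable HSPC fraction", {
  scr <- small_screen()
  summ <- scr$summ
  dw <- summ[!is.na(summ$drug) & summ$drug == "sm01"]
  cw <- summ[summ$role == "DMSO"]
  # survival 0.5 roughly halves the viable HSPC fraction
  ratio <- mean(dw$frac_hspc) / mean(cw$frac_hspc)
  expect_lt(ratio, 0.75)
  expect_gt(ratio, 0.3)
})

test_that("gene sets plant block members exactly, decoys stay disjoint", {
  u <- protein_universe(100)
  blk <- effect_block("anchor_coregulated", c("MCM4", "MCM7", u[10:17]),
                      anchors = c("MCM4", "MCM7"))
  cfg <- sim_config(n_proteins = 100, blocks = list(blk))
  sets <- simulate_genesets(cfg, 4, n_decoys = 6)
  expect_setequal(sets$set_anchor_coregulated_1, blk$proteins)
  dec <- unlist(sets[grep("^decoy_", names(sets))])
  expect_length(intersect(dec, blk$proteins), 0)
  expect_identical(sets, simulate_genesets(cfg, 4, n_decoys = 6))
})

test_that("interaction scores separate planted from decoy edges", {
  u <- protein_universe(100)
  blk <- effect_block("anchor_coregulated", u[10:19], anchors = NULL)
  cfg <- sim_config(n_proteins = 100, blocks = list(blk))
  ed <- simulate_interactions(cfg, 4)
  expect_true(all(ed$score[ed$planted] > 0.7))
  expect_true(all(ed$score[!ed$planted] < 0.7))
  expect_true(all(ed$protein_a[ed$planted] %in% blk$proteins))
  expect_false(any(ed$protein_a == ed$protein_b))
})

test_that("simulate_study writes a byte-identical file interface per seed", {
  u <- protein_universe(40)
  cfg <- sim_config(n_per_group = c(HD = 2, `ET-CALR` = 2, `ET-JAK2` = 2,
                                    `MF-CALR` = 2, `MF-JAK2` = 2),
                    n_proteins = 40, cells_per_well = 50,
                    drug_library = default_drug_library(2, 1, 1),
                    blocks = list(effect_block("anchor_coregulated",
                                               c("MCM4", "MCM7", u[10:13]),
                                               anchors = c("MCM4", "MCM7"))))
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  simulate_study(cfg, 21, d1)
  simulate_study(cfg, 21, d2)
  files <- list.files(d1)
  expect_true(all(c("clinical.tsv", "cells.tsv", "plate_layout.tsv",
                    "proteome_granulocyte.tsv", "sets.gmt", "edges.tsv",
                    "truth.json") %in% files))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # round trips
  m <- read_intensity_matrix(file.path(d1, "proteome_granulocyte.tsv"))
  expect_true(is.matrix(m) && "MCM4" %in% rownames(m))
  sets <- read_gmt(file.path(d1, "sets.gmt"))
  expect_true("set_anchor_coregulated_1" %in% names(sets))
  unlink(c(d1, d2), recursive = TRUE)
})
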