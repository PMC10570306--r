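# a response table where drug dX response tracks protein pSens exactly
.resp_table <- function(pts, ss, drug = "dX", readout = "HSPC") {
  data.frame(patient_id = pts, drug = drug, readout = readout,
             r = 0.1, p = 0.5, signed_sig = ss,
             class = "non-responder", valid = TRUE, stringsAsFactors = FALSE)
}

test_that("drug_protein_correlation finds a perfectly tracking protein", {
  set.seed(30)
  pts <- sprintf("PT%03d", 1:12)
  m <- matrix(rnorm(30 * 12, 20), 30, 12,
              dimnames = list(paste0("p", 1:30), pts))
  ss <- as.numeric(m["p1", ])             # response = protein p1
  resp <- .resp_table(pts, ss)
  sets <- list(hitset = paste0("p", 1:6), decoy = paste0("p", 21:26))
  out <- drug_protein_correlation(resp, m, sets, n_perm = 200, seed = 3)
  co <- out$correlations
  expect_equal(co$rho[co$protein == "p1"], 1)
  expect_true(all(abs(co$rho) <= 1))
  expect_equal(out$enrichment$set[out$enrichment$drug == "dX"][1:2],
               c("hitset", "decoy"))
  # constant responses are skipped with a warning
  expect_warning(
    out0 <- drug_protein_correlation(.resp_table(pts, rep(1, 12)), m, sets),
    "constant")
  expect_null(out0$correlations)
})

test_that("drug_clinical_anova counts planted factor associations", {
  pts <- sprintf("PT%03d", 1:20)
  cl <- data.frame(patient_id = pts,
                   cohort = rep(c("HD", "MF"), each = 10),
                   vaf = c(rep(0, 10), seq(20, 90, length.out = 10)),
                   stringsAsFactors = FALSE)
  set.seed(31)
  # MF patients respond strongly, HD not at all
  ss <- c(rnorm(10, 0, 0.1), rnorm(10, 3, 0.1))
  resp <- .resp_table(pts, ss)
  out <- drug_clinical_anova(resp, cl, factors = c("cohort", "vaf"))
  tab <- out$table
  expect_lt(tab$p[tab$factor == "cohort"], 1e-6)
  expect_equal(tab$direction[tab$factor == "cohort"], "resistance")
  # HD (first level) has the lower mean -> labeled resistance for level order,
  # while the continuous VAF slope is positive -> sensitivity
  expect_equal(tab$direction[tab$factor == "vaf"], "sensitivity")
  expect_equal(out$counts$n_sensitivity[out$counts$factor == "vaf"], 1)
  # constant factor contributes no rows
  cl$flat <- 1
  out2 <- drug_clinical_anova(resp, cl, factors = "flat")
  expect_null(out2$table)
})

test_that("responder_proteome separates a planted responder block", {
  set.seed(32)
  pts <- sprintf("PT%03d", 1:16)
  m <- matrix(rnorm(40 * 16, 20), 40, 16,
              dimnames = list(paste0("p", 1:40), pts))
  responders <- pts[1:6]
  m[1:5, pts %in% responders] <- m[1:5, pts %in% responders] + 3
  resp <- .resp_table(pts, ss = rep(1, 16))
  resp$class <- ifelse(pts %in% responders, "responder", "non-responder")
  resp$p <- ifelse(pts %in% responders, 0.01, 0.5)
  resp$r <- 0.3
  sets <- list(upset = paste0("p", 1:5), decoy = paste0("p", 31:35))
  out <- responder_proteome(resp, m, drugs = "dX", sets = sets,
                            n_perm = 200, seed = 4)
  expect_setequal(out$responders, responders)
  expect_true(all(out$table$p[1:5] < 0.01))
  expect_true(all(out$table$log2fc[1:5] > 2))
  en <- out$enrichment
  expect_equal(en$direction[en$set == "upset"], "positive")
  expect_lt(en$p[en$set == "upset"], 0.05)
  expect_error(responder_proteome(resp[resp$class != "responder", ], m, "dX"),
               "responder group smaller")
})

test_that("replicative signature recovers the MCM-anchored block", {
  set.seed(33)
  n <- 30
  pts <- sprintf("PT%03d", 1:n)
  u <- c("MCM4", "MCM7", paste0("q", 1:38))
  latent <- rnorm(n)
  mk <- function() {
    m <- matrix(rnorm(40 * n, 20, 1), 40, n, dimnames = list(u, pts))
    m[1:10, ] <- m[1:10, ] + 2 * rep(latent, each = 10)  # co-regulated block
    m["q20", ] <- 20 - 2 * latent + rnorm(n, 0, 0.2)     # anti-correlated
    m
  }
  mats <- list(granulocyte = mk(), HSPC = mk())
  out <- derive_replicative_signature(mats, k = 10)
  expect_setequal(out$signature, u[1:10])
  expect_true(all(c("MCM4", "MCM7") %in% out$signature[1:5]))
  expect_false("q20" %in% out$signature)
  expect_lt(out$avg_cor["q20"], -0.5)
  # k = 2 returns the anchors themselves
  expect_setequal(derive_replicative_signature(mats, k = 2)$signature,
                  c("MCM4", "MCM7"))
  # missing anchors in one cell type excludes it with a warning
  m2 <- mats; rownames(m2$HSPC)[1] <- "zz"
  expect_warning(out2 <- derive_replicative_signature(m2, k = 10),
                 "anchors missing")
  expect_equal(ncol(out2$per_cell_type), 1L)
})

test_that("categorize_mcm splits ranked patients into ordered tertiles", {
  pts <- sprintf("PT%03d", 1:9)
  m <- matrix(20, 4, 9, dimnames = list(c("MCM4", "MCM7", "a", "b"), pts))
  m["MCM4", ] <- m["MCM7", ] <- 20 + 1:9   # strictly increasing activity
  out <- categorize_mcm(list(granulocyte = m))
  expect_equal(out$mcm_category, rep(c("low", "medium", "high"), each = 3))
  expect_equal(out$patient_id, pts)        # order preserved by rank
  # a patient quantified in only one cell type is still categorized
  m2 <- m[, 1:5]
  out2 <- categorize_mcm(list(granulocyte = m, HSPC = m2))
  expect_equal(out2$n_cell_types[out2$patient_id == "PT006"], 1)
  expect_equal(nrow(out2), 9L)
})

test_that("signature scores and drug correlation behave as Pearson", {
  set.seed(34)
  pts <- sprintf("PT%03d", 1:14)
  m <- matrix(rnorm(20 * 14, 20), 20, 14,
              dimnames = list(paste0("p", 1:20), pts))
  sc <- signature_scores(m, paste0("p", 1:5))
  # z-scored means: cohort mean 0
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  manual <- colMeans((m[1:5, ] - rowMeans(m[1:5, ])) /
                       apply(m[1:5, ], 1, sd))
  expect_equal(sc, manual)
  # a response equal to the score correlates at exactly 1
  resp <- .resp_table(pts, ss = as.numeric(sc))
  out <- signature_drug_correlation(sc, resp)
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-10)
  ref <- cor.test(sc, sc + rnorm(14))  # API sanity on noisy variant
  expect_error(signature_scores(m, "nope"), "no signature proteins")
})

test_that("vaf_correlation recovers a planted VAF-scaled block", {
  set.seed(35)
  n <- 24
  pts <- sprintf("PT%03d", 1:n)
  cl <- data.frame(patient_id = pts, driver = "CALR",
                   cohort = rep(c("ET", "MF"), each = 12),
                   vaf = runif(n, 20, 95), stringsAsFactors = FALSE)
  cl$homozygous <- cl$vaf >= 75
  m <- matrix(rnorm(30 * n, 20), 30, n,
              dimnames = list(paste0("p", 1:30), pts))
  m[1:5, ] <- m[1:5, ] + 0.05 * rep(cl$vaf, each = 5)
  sets <- list(vafset = paste0("p", 1:5), decoy = paste0("p", 21:25))
  out <- vaf_correlation(m, cl, "CALR", sets = sets, n_perm = 200, seed = 5)
  expect_true(all(out$table$r[1:5] > 0.5))
  expect_true(all(paste0("p", 1:5) %in% out$significant))
  # per-protein Pearson p matches cor.test
  ref <- cor.test(m[1, ], cl$vaf)
  expect_equal(out$table$p[1], ref$p.value, tolerance = 1e-10)
  en <- out$enrichment
  expect_lt(en$p[en$set == "vafset"], 0.05)
  expect_equal(nrow(out$anova), 30L)
  expect_error(vaf_correlation(m, transform(cl, vaf = 50), "CALR"),
               "constant")
})

test_that("subgroup differential isolates a homozygous-specific drug", {
  pts <- sprintf("PT%03d", 1:12)
  cl <- data.frame(patient_id = pts,
                   driver = rep(c("CALR", "CALR", "JAK2"), each = 4),
                   homozygous = c(rep(TRUE, 4), rep(FALSE, 8)),
                   stringsAsFactors = FALSE)
  grp_ss <- c(rep(3, 4), rep(0.5, 4), rep(0.2, 4))
  resp <- rbind(.resp_table(pts, grp_ss, drug = "dHom", readout = "oncogenic"),
                .resp_table(pts, rep(1, 12), drug = "dNull",
                            readout = "oncogenic"))
  out <- subgroup_drug_differential(resp, cl)
  hom <- out[out$drug == "dHom", ]
  expect_equal(hom$delta_vs_het_calr, 2.5)
  expect_equal(hom$delta_vs_jak2, 2.8)
  expect_equal(hom$n_hom, 4)
  nul <- out[out$drug == "dNull", ]
  expect_equal(nul$delta_vs_het_calr, 0)
  expect_equal(nul$delta_vs_jak2, 0)
  # too-small groups produce NA deltas
  cl2 <- cl; cl2$homozygous <- c(TRUE, rep(FALSE, 11))
  out2 <- subgroup_drug_differential(resp, cl2)
  expect_true(all(is.na(out2$delta_vs_het_calr)))
})
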