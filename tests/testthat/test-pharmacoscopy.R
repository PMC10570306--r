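test_that("ttest_pooled matches t.test(var.equal = TRUE)", {
  set.seed(1)
  x <- rnorm(7); y <- rnorm(9, 0.5)
  ref <- t.test(x, y, var.equal = TRUE)
  got <- ttest_pooled(x, y)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, unname(ref$parameter))
})

test_that("ttest_pooled handles degenerate inputs by fixed rules", {
  expect_equal(ttest_pooled(c(1, 1), c(1, 1))$p, 1)
  expect_equal(ttest_pooled(c(2, 2), c(1, 1))$p, .Machine$double.xmin)
  expect_error(ttest_pooled(numeric(0), 1), "non-empty")
  expect_true(is.na(ttest_pooled(1, 1)$t))
})

test_that("row_ttest agrees with per-row t.test", {
  set.seed(2)
  m <- matrix(rnorm(8 * 10), 8, dimnames = list(paste0("p", 1:8), NULL))
  tab <- row_ttest(m, 1:5, 6:10)
  for (i in c(1, 4, 8)) {
    ref <- t.test(m[i, 1:5], m[i, 6:10], var.equal = TRUE)
    expect_equal(tab$t[i], unname(ref$statistic))
    expect_equal(tab$p[i], ref$p.value)
  }
  expect_equal(tab$signed_sig, sign(tab$log2fc) * -log10(tab$p))
})

test_that("classifier recovers truth labels on separable channels", {
  scr <- small_screen()
  cells <- scr$pharm$cells[1:20000]
  clf <- train_cell_classifier(cells, seed = 1)
  expect_gt(clf$report$accuracy, 0.85)
  expect_gt(clf$report$viability_accuracy, 0.95)
  expect_true(all(clf$report$sensitivity > 0.5))
  gated <- classify_and_gate(cells, clf)
  expect_true(all(gated$cell_class %in%
                    c("HSPC", "T-cell", "monocyte", "other")))
  expect_equal(nrow(gated) + attr(gated, "n_removed"), nrow(cells))
})

test_that("classifier on shuffled labels degrades to chance", {
  scr <- small_screen()
  cells <- data.table::copy(scr$pharm$cells[1:8000])
  set.seed(99)
  cells[, true_class := sample(true_class)]
  clf <- suppressWarnings(train_cell_classifier(cells, seed = 1))
  # four classes with unequal priors: accuracy must collapse towards the
  # majority-class rate, far below the separable-channel accuracy
  expect_lt(clf$report$accuracy, 0.65)
})

test_that("classify_and_gate truth bypass and empty input behave", {
  scr <- small_screen()
  cells <- scr$pharm$cells[1:1000]
  gated <- classify_and_gate(cells, use_truth = TRUE)
  expect_true(all(gated$true_viable))
  expect_identical(gated$cell_class, gated$true_class)
  empty <- classify_and_gate(cells[0])
  expect_equal(nrow(empty), 0L)
  expect_true("cell_class" %in% names(empty))
  expect_error(classify_and_gate(cells, classifier = NULL), "cell_classifier")
})

test_that("well summaries report exact fractions on a constructed well", {
  cells <- data.table::data.table(
    patient_id = "PTX", plate = "PL", well = "W001",
    drug = NA_character_, drug_class = "control",
    concentration = NA_real_, role = "DMSO", control_type = "DMSO",
    cell_class = rep(c("HSPC", "T-cell", "monocyte", "other"),
                     c(10, 40, 20, 30)),
    ch_onco = rep(c(100, 10, 100, 50), c(10, 40, 20, 30)))
  summ <- summarize_wells(cells, policy = "truth", threshold = 60)
  expect_equal(summ$n_viable, 100L)
  expect_equal(summ$frac_hspc, 0.1)
  expect_equal(summ$frac_tcell, 0.4)
  expect_equal(summ$frac_mono, 0.2)
  expect_equal(summ$frac_other, 0.3)
  expect_equal(summ$onco_pos_frac, 0.3)  # HSPC + monocyte above 60
  expect_true(summ$valid)
})

test_that("midpoint threshold sits between T-cell and HSPC onco medians", {
  scr <- small_screen()
  thr <- attr(scr$summ, "thresholds")
  cells <- scr$gated
  for (p in thr$patient_id[1:3]) {
    ctrl <- cells[cells$patient_id == p & cells$role != "drug"]
    mt <- median(ctrl$ch_onco[ctrl$cell_class == "T-cell"])
    mh <- median(ctrl$ch_onco[ctrl$cell_class == "HSPC"])
    expect_equal(thr$thr[thr$patient_id == p], (mt + mh) / 2)
  }
  # the derived threshold should land near the generative truth (60)
  expect_true(all(thr$thr > 30 & thr$thr < 120))
})

test_that("QC threshold is closed at 0.3% and flags planted-low patients", {
  scr <- small_screen()
  qc <- qc_patients(scr$summ)
  expect_setequal(c(qc$included, qc$excluded), scr$clinical$patient_id)
  expect_length(qc$excluded, 0)  # no planted-low patients in this screen
  # boundary behavior on a constructed summary
  mk <- function(f) data.table::data.table(
    patient_id = "PTB", role = "DMSO", valid = TRUE, frac_hspc = f,
    drug = NA_character_)
  expect_length(qc_patients(rbind(mk(0.003), mk(0.003)))$excluded, 0)
  expect_length(qc_patients(rbind(mk(0.0029), mk(0.0029)))$included, 0)
  expect_error(qc_patients(scr$summ[scr$summ$role == "drug"]),
               "without control wells")
})

test_that("score_drug reproduces the hand-computed toy example", {
  well <- function(w, role, drug, f) data.table::data.table(
    patient_id = "PTX", well = w, drug = drug,
    concentration = if (is.na(drug)) NA_real_ else 1,
    role = role, control_type = "DMSO", frac_hspc = f,
    onco_pos_frac = 0.5, valid = TRUE)
  summ <- rbind(well("W1", "drug", "dA", 0.010), well("W2", "drug", "dA", 0.030),
                well("W3", "DMSO", NA, 0.030), well("W4", "DMSO", NA, 0.050))
  sc <- score_drug(summ, "PTX", "dA")
  # r = 1 - mean(0.01, 0.03)/mean(0.03, 0.05) = 1 - 0.02/0.04 = 0.5
  expect_equal(sc$r, 0.5)
  # pooled t by hand: d = -0.02, sp2 = (2e-4 + 2e-4)/2, se = sp2*(1/2+1/2)
  se <- sqrt(2e-4)
  t_hand <- -0.02 / se
  expect_equal(sc$p, 2 * pt(-abs(t_hand), 2))
  expect_equal(sc$signed_sig, -log10(sc$p))
  expect_true(sc$valid)
})

test_that("identical drug and control wells give the null score", {
  well <- function(w, role, drug) data.table::data.table(
    patient_id = "PTX", well = w, drug = drug,
    concentration = if (is.na(drug)) NA_real_ else 1,
    role = role, control_type = "DMSO", frac_hspc = 0.04, valid = TRUE)
  summ <- rbind(well("W1", "drug", "dA"), well("W2", "drug", "dA"),
                well("W3", "DMSO", NA), well("W4", "DMSO", NA))
  sc <- score_drug(summ, "PTX", "dA")
  expect_equal(sc$r, 0)
  expect_equal(sc$p, 1)
  expect_equal(sc$signed_sig, 0)
  expect_equal(sc$class, "non-responder")
})

test_that("scoring pools concentrations and matches control types", {
  scr <- small_screen()
  p1 <- scr$clinical$patient_id[1]
  sc <- score_drug(scr$summ, p1, "bio01", per_concentration = TRUE)
  pc <- attr(sc, "per_concentration")
  expect_equal(sort(pc$concentration), c(0.1, 1, 10))
  # pooled r is the well-count-weighted view of per-concentration means
  dw <- scr$summ[scr$summ$patient_id == p1 & !is.na(scr$summ$drug) &
                   scr$summ$drug == "bio01" & scr$summ$valid]
  cw <- scr$summ[scr$summ$patient_id == p1 & scr$summ$role == "PBS" &
                   scr$summ$valid]
  expect_equal(sc$r, 1 - mean(dw$frac_hspc) / mean(cw$frac_hspc))
  expect_error(score_drug(scr$summ, p1, "nonexistent"), "no drug wells")
  expect_error(score_drug(scr$summ, p1, "sm01", readout = "bogus"),
               "unknown readout")
})

test_that("classify_response covers all branches", {
  expect_equal(classify_response(0.3, 0.01), "responder")
  expect_equal(classify_response(0.3, 0.2), "non-responder")
  expect_equal(classify_response(-0.3, 0.01), "resistant")
  expect_equal(classify_response(-0.3, 0.2), "non-responder")
  expect_equal(classify_response(-0.3, 0.2, strict_resistant = FALSE),
               "resistant")
  expect_true(is.na(classify_response(NA, 0.01)))
})

test_that("planted effect is recovered as responders by score_all_drugs", {
  scr <- small_screen()
  resp <- score_all_drugs(scr$summ, readouts = "HSPC")
  hit <- resp[resp$drug == "sm01", ]
  other <- resp[resp$drug != "sm01", ]
  expect_gt(median(hit$r), 0.25)
  expect_gt(mean(hit$class == "responder"), 0.8)
  expect_lt(mean(other$class == "responder", na.rm = TRUE), 0.2)
})

test_that("cohort_summary aggregates signed significances per stratum", {
  scr <- small_screen()
  resp <- score_all_drugs(scr$summ)
  cs <- cohort_summary(resp, scr$clinical, stratum_col = "driver")
  expect_setequal(unique(cs$stratum), unique(scr$clinical$driver))
  # hand-check one cell of the aggregation
  row <- cs[cs$drug == "sm01" & cs$stratum == "CALR", ]
  pts <- scr$clinical$patient_id[scr$clinical$driver == "CALR"]
  ref <- resp[resp$drug == "sm01" & resp$readout == "HSPC" &
                resp$patient_id %in% pts & resp$valid, ]
  expect_equal(row$mean_signed_sig_HSPC, mean(ref$signed_sig))
  expect_true(all(cs$frac_sig_on_target >= 0 & cs$frac_sig_on_target <= 1))
})
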