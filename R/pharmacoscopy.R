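#' Train a feature-based single-cell classifier
#'
#' Two-stage classifier over mean-channel features (log intensities of the
#' nuclear, lineage, CD34 and oncogenic channels plus log nuclear area): a
#' logistic viability gate driven by nuclear morphology, and a multinomial
#' cell-class model (HSPC / T-cell / monocyte / other) trained on viable
#' cells. A held-out split provides accuracy and per-class sensitivity.
#'
#' @param cells single-cell table with channel columns and truth labels
#'   `true_class`, `true_viable`.
#' @param seed integer seed for the held-out split.
#' @param holdout fraction of cells held out for evaluation.
#' @return a `cell_classifier` object with a `report` (accuracy, viability
#'   accuracy, per-class sensitivity).
#' @export
train_cell_classifier <- function(cells, seed = 1L, holdout = 0.25) {
  cells <- data.table::as.data.table(cells)
  if (length(unique(cells$true_class)) < 2L)
    stop("need at least two cell classes to train")
  set.seed(stream_seed(seed, 6L))
  feats <- .cell_features(cells)
  n <- nrow(feats)
  test <- sample.int(n, max(1L, round(holdout * n)))
  train <- setdiff(seq_len(n), test)

  viab <- glm(cells$true_viable[train] ~ log_nuclear + log_area,
              data = feats[train, ], family = binomial())
  cls_train <- train[cells$true_viable[train]]
  cls_fit <- nnet::multinom(
    factor(cells$true_class[cls_train]) ~ log_lineage + log_cd34 + log_area,
    data = feats[cls_train, ], trace = FALSE, maxit = 300)

  # held-out report
  pv <- predict(viab, feats[test, ], type = "response") > 0.5
  viab_acc <- mean(pv == cells$true_viable[test])
  test_v <- test[cells$true_viable[test] & pv]
  pc <- as.character(predict(cls_fit, feats[test_v, ]))
  acc <- mean(pc == cells$true_class[test_v])
  sens <- vapply(sort(unique(cells$true_class[test_v])), function(k)
    mean(pc[cells$true_class[test_v] == k] == k), numeric(1))
  structure(list(viability = viab, classes = cls_fit,
                 report = list(accuracy = acc, viability_accuracy = viab_acc,
                               sensitivity = sens, n_test = length(test))),
            class = "cell_classifier")
}

.cell_features <- function(cells) {
  need <- c("ch_nuclear", "ch_lineage", "ch_cd34", "ch_onco", "nuclear_area")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  data.frame(log_nuclear = log1p(cells$ch_nuclear),
             log_lineage = log1p(cells$ch_lineage),
             log_cd34 = log1p(cells$ch_cd34),
             log_onco = log1p(cells$ch_onco),
             log_area = log1p(cells$nuclear_area))
}

#' Classify cells and gate to viable
#'
#' Applies the viability gate and the class model; only viable-called cells
#' are retained, each annotated with a `cell_class`. With
#' `use_truth = TRUE` the retained set and labels are taken from the truth
#' columns instead (identity gate for simulated data).
#'
#' @param cells single-cell table.
#' @param classifier a [train_cell_classifier()] fit (ignored when
#'   `use_truth = TRUE`).
#' @param use_truth bypass the classifier with truth labels.
#' @return data.table of viable cells with a `cell_class` column; the
#'   number of removed cells is attached as attribute `n_removed`.
#' @export
classify_and_gate <- function(cells, classifier = NULL, use_truth = FALSE) {
  cells <- data.table::as.data.table(cells)
  if (nrow(cells) == 0L) {
    out <- data.table::copy(cells)
    out[, cell_class := character(0)]
    return(out)
  }
  if (use_truth) {
    out <- cells[true_viable == TRUE]
    out[, cell_class := true_class]
  } else {
    if (!inherits(classifier, "cell_classifier"))
      stop("a trained cell_classifier is required unless use_truth = TRUE")
    feats <- .cell_features(cells)
    pv <- predict(classifier$viability, feats, type = "response") > 0.5
    out <- cells[pv]
    out[, cell_class := as.character(predict(classifier$classes, feats[pv, ]))]
  }
  data.table::setattr(out, "n_removed", nrow(cells) - nrow(out))
  out[]
}

#' Summarize gated cells per well
#'
#' Per well: viable cell count, cell-class fractions, oncogenic
#' marker-positive fraction among viable cells, and mean oncogenic intensity
#' per class. The positivity threshold follows the requested policy:
#' `"tcell_hspc_midpoint"` sets, per patient, the midpoint between the
#' median oncogenic intensity of T-cells and of HSPCs in that patient's
#' control wells (T-cells as the in-sample negative reference); `"truth"`
#' uses a fixed supplied threshold. Per-patient z-scored mean intensities
#' are attached per well. Wells with zero viable cells are flagged
#' (`valid = FALSE`) and excluded downstream.
#'
#' @param cells gated cells from [classify_and_gate()].
#' @param policy threshold policy.
#' @param threshold fixed threshold for `policy = "truth"`.
#' @return data.table, one row per patient x well, with attribute
#'   `thresholds` (per-patient threshold used).
#' @export
summarize_wells <- function(cells, policy = c("tcell_hspc_midpoint", "truth"),
                            threshold = NULL) {
  policy <- match.arg(policy)
  cells <- data.table::as.data.table(cells)
  if (policy == "tcell_hspc_midpoint") {
    ctrl <- cells[role != "drug"]
    med <- ctrl[cell_class %in% c("T-cell", "HSPC"),
                .(m = median(ch_onco)), by = .(patient_id, cell_class)]
    medw <- data.table::dcast(med, patient_id ~ cell_class, value.var = "m")
    thr <- medw[, .(patient_id, thr = (`T-cell` + HSPC) / 2)]
  } else {
    if (is.null(threshold)) stop("policy 'truth' needs a threshold")
    thr <- data.table::data.table(patient_id = unique(cells$patient_id),
                                  thr = threshold)
  }
  cells <- merge(cells, thr, by = "patient_id", sort = FALSE)

  # per-patient z-scoring of intensities across that patient's cells
  zcols <- c("ch_onco")
  cells[, z_onco := (ch_onco - mean(ch_onco)) / sd(ch_onco), by = patient_id]

  keys <- c("patient_id", "plate", "well", "drug", "drug_class",
            "concentration", "role", "control_type")
  keys <- intersect(keys, names(cells))
  summ <- cells[, {
    nv <- .N
    fr <- vapply(c("HSPC", "T-cell", "monocyte", "other"),
                 function(k) mean(cell_class == k), numeric(1))
    list(n_viable = nv,
         frac_hspc = fr[1], frac_tcell = fr[2], frac_mono = fr[3],
         frac_other = fr[4],
         onco_pos_frac = mean(ch_onco > thr[1]),
         mean_onco_hspc = mean(ch_onco[cell_class == "HSPC"]),
         mean_onco_tcell = mean(ch_onco[cell_class == "T-cell"]),
         mean_z_onco = mean(z_onco))
  }, by = keys]
  summ[, valid := n_viable > 0]
  data.table::setattr(summ, "thresholds", thr)
  summ[]
}

#' Patient-level quality control on control-well HSPC fractions
#'
#' A patient is excluded iff the mean HSPC fraction across its
#' vehicle-control wells falls below `min_hspc_fraction` (inclusion is
#' closed at the threshold). Patients lacking control wells are an error.
#'
#' @param summaries well summaries.
#' @param min_hspc_fraction inclusion threshold (default 0.003, i.e. 0.3%).
#' @return list: `included` and `excluded` patient ids, `report` data.frame
#'   with per-patient control HSPC fractions.
#' @export
qc_patients <- function(summaries, min_hspc_fraction = 0.003) {
  summ <- data.table::as.data.table(summaries)
  ctrl <- summ[role != "drug" & valid == TRUE]
  pts <- unique(summ$patient_id)
  if (!all(pts %in% ctrl$patient_id))
    stop("patient without control wells: ",
         paste(setdiff(pts, ctrl$patient_id), collapse = ", "))
  rep_ <- ctrl[, .(control_hspc_fraction = mean(frac_hspc)), by = patient_id]
  rep_[, included := control_hspc_fraction >= min_hspc_fraction]
  list(included = rep_$patient_id[rep_$included],
       excluded = rep_$patient_id[!rep_$included],
       report = as.data.frame(rep_))
}

#' Score one drug for one patient
#'
#' Relative reduction of a well-level readout in drug wells versus the
#' drug's matched vehicle-control wells (DMSO for small molecules, PBS for
#' biologics, isotype for antibodies): `r = 1 - mean(drug) / mean(control)`,
#' pooling all replicates and concentrations. Significance is a two-sided
#' pooled-variance Student's t-test on the well-level values, and
#' `signed_sig = sign(r) * -log10(p)` — positive for on-target depletion.
#'
#' @param summaries well summaries.
#' @param patient patient id.
#' @param drug drug name.
#' @param readout `"HSPC"`, `"oncogenic"`, or the name of any well-summary
#'   fraction column (arbitrary gated population).
#' @param alpha significance level carried into the response class.
#' @param per_concentration also return per-concentration diagnostics.
#' @return data.frame row: patient, drug, readout, `r`, `p`, `signed_sig`,
#'   `class`, `valid`; with attribute `per_concentration` if requested.
#' @export
score_drug <- function(summaries, patient, drug, readout = "HSPC",
                       alpha = 0.05, per_concentration = FALSE) {
  summ <- data.table::as.data.table(summaries)
  col <- switch(readout, HSPC = "frac_hspc", oncogenic = "onco_pos_frac",
                readout)
  if (!col %in% names(summ)) stop("unknown readout column: ", col)
  sel_d <- summ$patient_id == patient & !is.na(summ$drug) &
    summ$drug == drug & summ$valid
  dw <- summ[sel_d]
  if (nrow(dw) < 1L) stop("no drug wells for ", patient, " / ", drug)
  ctype <- dw$control_type[1]
  cw <- summ[summ$patient_id == patient & summ$role == ctype & summ$valid]
  if (nrow(cw) < 2L) stop("need >= 2 matched control wells")
  x <- dw[[col]]; y <- cw[[col]]
  mc <- mean(y)
  valid <- is.finite(mc) && mc != 0
  r <- if (valid) 1 - mean(x) / mc else NA_real_
  tt <- ttest_pooled(x, y)
  ss <- if (valid) signed_significance(tt$p, r) else NA_real_
  out <- data.frame(patient_id = patient, drug = drug, readout = readout,
                    r = r, p = tt$p, signed_sig = ss,
                    class = if (valid) classify_response(r, tt$p, alpha) else NA_character_,
                    valid = valid, stringsAsFactors = FALSE)
  if (per_concentration) {
    pc <- dw[, .(r = 1 - mean(.SD[[col]]) / mc,
                 p = ttest_pooled(.SD[[col]], y)$p), by = concentration]
    attr(out, "per_concentration") <- as.data.frame(pc)
  }
  out
}

#' Classify a drug response
#'
#' Responder: significant on-target response (p < alpha, r > 0).
#' Resistant: significant off-target response (p < alpha, r < 0).
#' Everything else (including non-significant off-target): non-responder.
#' Setting `strict_resistant = FALSE` instead labels any off-target
#' direction resistant.
#'
#' @param r relative reduction.
#' @param p p-value.
#' @param alpha significance level.
#' @param strict_resistant see above.
#' @return `"responder"`, `"non-responder"` or `"resistant"`.
#' @export
classify_response <- function(r, p, alpha = 0.05, strict_resistant = TRUE) {
  if (is.na(r) || is.na(p)) return(NA_character_)
  if (p < alpha && r > 0) return("responder")
  if (r < 0 && (p < alpha || !strict_resistant)) return("resistant")
  "non-responder"
}

#' Score all patient x drug x readout combinations
#'
#' @param summaries well summaries.
#' @param readouts readouts to score.
#' @param patients patients to score (default: all with valid wells).
#' @param alpha significance level.
#' @return data.frame of [score_drug()] rows.
#' @export
score_all_drugs <- function(summaries, readouts = c("HSPC", "oncogenic"),
                            patients = NULL, alpha = 0.05) {
  summ <- data.table::as.data.table(summaries)
  if (is.null(patients)) patients <- unique(summ$patient_id)
  drugs <- unique(summ$drug[!is.na(summ$drug)])
  grid <- expand.grid(patient_id = patients, drug = drugs, readout = readouts,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    score_drug(summ, grid$patient_id[i], grid$drug[i], grid$readout[i], alpha))
  do.call(rbind, out)
}

#' Cohort-level drug-response summary
#'
#' Per drug and stratum: mean signed significance per readout, and the
#' fraction of patients with a significant on-target effect averaged across
#' the two readouts. Invalid responses are excluded; empty strata are
#' dropped with a warning.
#'
#' @param responses output of [score_all_drugs()].
#' @param clinical clinical table (for strata).
#' @param stratum_col clinical column to stratify by (e.g. `"driver"`).
#' @param alpha significance level for the on-target fraction.
#' @return data.frame: drug, stratum, mean signed_sig per readout,
#'   `frac_sig_on_target`.
#' @export
cohort_summary <- function(responses, clinical, stratum_col = "driver",
                           alpha = 0.05) {
  resp <- data.table::as.data.table(responses)[valid == TRUE]
  resp <- merge(resp,
                data.table::as.data.table(clinical)[, .(patient_id,
                                                        stratum = get(stratum_col))],
                by = "patient_id")
  if (nrow(resp) == 0L) {
    warning("no valid responses in any stratum")
    return(data.frame())
  }
  per_read <- resp[, .(mean_signed_sig = mean(signed_sig),
                       frac_sig = mean(p < alpha & r > 0)),
                   by = .(drug, stratum, readout)]
  wide <- data.table::dcast(per_read, drug + stratum ~ readout,
                            value.var = c("mean_signed_sig", "frac_sig"))
  fs_cols <- grep("^frac_sig_", names(wide), value = TRUE)
  wide[, frac_sig_on_target := rowMeans(.SD), .SDcols = fs_cols]
  as.data.frame(wide)
}
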