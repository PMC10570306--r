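#' Correlate drug responses with protein levels, with enrichment
#'
#' For each drug: Spearman correlation (average-rank ties) of the
#' patient-level HSPC drug response (signed significance) with each
#' protein's level across the shared patients, preranked enrichment on the
#' correlation vector, and per-set counts of drugs with significant
#' positive / negative enrichment.
#'
#' @param responses [score_all_drugs()] table (HSPC readout rows used).
#' @param mat proteins x patients matrix (columns named by patient id).
#' @param sets gene-set list.
#' @param readout readout to correlate.
#' @param min_patients minimal shared patients per drug.
#' @param alpha enrichment significance level for counting.
#' @param n_perm,seed enrichment null parameters.
#' @return list: `correlations` (data.frame drug/protein/rho), `enrichment`
#'   (per drug x set), `counts` (per set: n_sensitivity, n_resistance).
#' @export
drug_protein_correlation <- function(responses, mat, sets, readout = "HSPC",
                                     min_patients = 5, alpha = 0.05,
                                     n_perm = 500, seed = 1L) {
  resp <- responses[responses$readout == readout & responses$valid, ]
  drugs <- unique(resp$drug)
  cor_rows <- list(); enr_rows <- list()
  for (dg in drugs) {
    rd <- resp[resp$drug == dg, ]
    shared <- intersect(rd$patient_id, colnames(mat))
    if (length(shared) < min_patients) next
    v <- rd$signed_sig[match(shared, rd$patient_id)]
    if (sd(v) == 0) { warning("constant response vector; skipping ", dg); next }
    rho <- as.numeric(cor(t(mat[, shared, drop = FALSE]), v,
                          method = "spearman"))
    names(rho) <- rownames(mat)
    cor_rows[[dg]] <- data.frame(drug = dg, protein = names(rho), rho = rho,
                                 row.names = NULL, stringsAsFactors = FALSE)
    enr <- gsea_preranked(rho, sets, n_perm = n_perm, seed = seed)
    if (nrow(enr)) { enr$drug <- dg; enr_rows[[dg]] <- enr }
  }
  enrichment <- if (length(enr_rows)) do.call(rbind, enr_rows) else NULL
  counts <- NULL
  if (!is.null(enrichment)) {
    sig <- enrichment[enrichment$p < alpha, ]
    counts <- aggregate(cbind(n_sensitivity = sig$es > 0,
                              n_resistance = sig$es < 0),
                        by = list(set = sig$set), FUN = sum)
  }
  list(correlations = do.call(rbind, cor_rows), enrichment = enrichment,
       counts = counts)
}

#' Count significant drug-response associations with clinical factors
#'
#' Per drug x readout x factor: one-way ANOVA (or regression for continuous
#' factors) of the patient signed significances on the factor. Significant
#' associations (p < alpha) are counted per factor, split into sensitivity
#' (factor level / slope associated with stronger on-target response) and
#' resistance.
#'
#' @param responses [score_all_drugs()] table.
#' @param clinical clinical table.
#' @param factors character vector of clinical column names.
#' @param alpha significance level.
#' @return list: `table` (per drug x readout x factor: p, direction),
#'   `counts` (per factor: n_sensitivity, n_resistance).
#' @export
drug_clinical_anova <- function(responses, clinical, factors, alpha = 0.05) {
  resp <- merge(responses[responses$valid, ], clinical, by = "patient_id")
  rows <- list()
  for (f in factors) {
    for (dg in unique(resp$drug)) {
      for (ro in unique(resp$readout)) {
        sub <- resp[resp$drug == dg & resp$readout == ro, ]
        v <- sub[[f]]
        if (is.character(v) || is.logical(v)) v <- factor(v)
        if (is.factor(v)) {
          v <- droplevels(v)
          keepl <- names(which(table(v) >= 2))
          keep <- v %in% keepl
          sub <- sub[keep, ]; v <- droplevels(factor(v[keep]))
          if (nlevels(v) < 2) next
          fit <- stats::aov(sub$signed_sig ~ v)
          p <- summary(fit)[[1]][["Pr(>F)"]][1]
          mns <- tapply(sub$signed_sig, v, mean)
          dirn <- if (which.max(mns) == 1L) 1 else -1
        } else {
          if (sd(v) == 0) next
          ct <- suppressWarnings(cor.test(v, sub$signed_sig))
          p <- ct$p.value
          dirn <- sign(ct$estimate)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          drug = dg, readout = ro, factor = f, p = p,
          direction = ifelse(dirn >= 0, "sensitivity", "resistance"),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  counts <- data.frame(factor = character(0), n_sensitivity = integer(0),
                       n_resistance = integer(0))
  if (!is.null(tab)) {
    sig <- tab[!is.na(tab$p) & tab$p < alpha, ]
    if (nrow(sig))
      counts <- aggregate(cbind(n_sensitivity = sig$direction == "sensitivity",
                                n_resistance = sig$direction == "resistance"),
                          by = list(factor = sig$factor), FUN = sum)
  }
  list(table = tab, counts = counts)
}

#' Responder proteome comparison with enrichment
#'
#' Defines the responder group from [classify_response()] classes (for a
#' single drug, or pooled over a drug class by requiring a responder call
#' for at least `min_class_hits` class members), performs a per-protein
#' Student's t-test of responders versus everyone else, and runs preranked
#' enrichment on the signed -log10 p ranking.
#'
#' @param responses [score_all_drugs()] table (HSPC readout used).
#' @param mat proteins x patients matrix.
#' @param drugs drug name(s) defining the comparison.
#' @param sets gene-set list (NULL skips enrichment).
#' @param min_class_hits responder calls required across `drugs`.
#' @param min_responders minimal responder-group size.
#' @param n_perm,seed enrichment parameters.
#' @return list: `responders`, `table` (volcano), `enrichment`.
#' @export
responder_proteome <- function(responses, mat, drugs, sets = NULL,
                               min_class_hits = 3, min_responders = 3,
                               n_perm = 500, seed = 1L) {
  resp <- responses[responses$readout == "HSPC" & responses$valid &
                      responses$drug %in% drugs, ]
  hits <- tapply(resp$class == "responder", resp$patient_id, sum)
  need <- if (length(drugs) == 1L) 1L else min_class_hits
  responders <- names(hits)[hits >= need]
  pts <- intersect(unique(resp$patient_id), colnames(mat))
  responders <- intersect(responders, pts)
  rest <- setdiff(pts, responders)
  if (length(responders) < min_responders)
    stop("responder group smaller than ", min_responders)
  if (length(rest) < 2L) stop("non-responder group too small")
  tab <- row_ttest(mat[, pts, drop = FALSE],
                   match(responders, pts), match(rest, pts))
  names(tab)[1] <- "protein"
  enr <- NULL
  if (!is.null(sets)) {
    rk <- stats::setNames(tab$signed_sig, tab$protein)
    enr <- gsea_preranked(rk, sets, n_perm = n_perm, seed = seed)
  }
  list(responders = responders, table = tab, enrichment = enr)
}

#' Derive the replicative (MCM-anchored) protein signature
#'
#' Per cell type, correlates every protein with the mean level of the
#' anchor proteins (MCM4/MCM7); averages the correlations across cell types
#' over proteins quantified in all of them; returns the top-k proteins by
#' average correlation (anchors rank first by construction).
#'
#' @param mats named list of proteins x patients matrices per cell type.
#' @param anchors anchor protein names.
#' @param k signature size.
#' @param normalize_hd optional named group vector + `"HD"` median
#'   subtraction: supply `groups` (per column of each matrix) to normalize
#'   by subtracting the median healthy-donor expression per protein.
#' @param groups optional per-patient group labels (named by patient id).
#' @return list: `signature` (k proteins), `avg_cor` (named, all shared
#'   proteins), `per_cell_type` (correlation matrix).
#' @export
derive_replicative_signature <- function(mats, anchors = c("MCM4", "MCM7"),
                                         k = 50, groups = NULL,
                                         normalize_hd = FALSE) {
  cors <- list()
  for (ct in names(mats)) {
    m <- mats[[ct]]
    if (!all(anchors %in% rownames(m))) {
      warning("anchors missing in ", ct, "; cell type excluded")
      next
    }
    if (normalize_hd && !is.null(groups)) {
      hd <- colnames(m)[groups[colnames(m)] == "HD"]
      if (length(hd)) m <- m - apply(m[, hd, drop = FALSE], 1L, median)
    }
    anchor_mean <- colMeans(m[anchors, , drop = FALSE])
    r <- as.numeric(cor(t(m), anchor_mean))
    cors[[ct]] <- stats::setNames(r, rownames(m))
  }
  if (!length(cors)) stop("no cell type carries the anchors")
  shared <- Reduce(intersect, lapply(cors, names))
  cm <- vapply(cors, function(x) x[shared], numeric(length(shared)))
  avg <- rowMeans(cm)
  ord <- order(-avg, shared, method = "radix")
  sig <- shared[ord][seq_len(min(k, length(shared)))]
  list(signature = sig, avg_cor = stats::setNames(avg, shared)[ord],
       per_cell_type = cm)
}

#' Categorize patients by replicative (MCM) activity
#'
#' Per patient and cell type, the mean anchor level is ranked within the
#' cell type; ranks are averaged across the cell types in which the patient
#' is quantified, and the averaged ranks are split into tertiles
#' low / medium / high (ties broken by patient id).
#'
#' @param mats named list of proteins x patients matrices.
#' @param anchors anchor protein names.
#' @return data.frame: `patient_id`, `n_cell_types`, `avg_rank`,
#'   `mcm_category`.
#' @export
categorize_mcm <- function(mats, anchors = c("MCM4", "MCM7")) {
  ranks <- list()
  for (ct in names(mats)) {
    m <- mats[[ct]]
    if (!all(anchors %in% rownames(m))) next
    sc <- colMeans(m[anchors, , drop = FALSE])
    ranks[[ct]] <- stats::setNames(rank(sc), names(sc))
  }
  pts <- sort(unique(unlist(lapply(ranks, names))))
  if (!length(pts)) stop("no patient carries the anchors in any cell type")
  avg <- vapply(pts, function(p) {
    v <- unlist(lapply(ranks, function(r) r[p]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  ncts <- vapply(pts, function(p)
    sum(vapply(ranks, function(r) p %in% names(r), logical(1))), numeric(1))
  ord <- order(avg, pts, method = "radix")
  tert <- cut(seq_along(pts), breaks = 3, labels = c("low", "medium", "high"))
  out <- data.frame(patient_id = pts[ord], n_cell_types = ncts[ord],
                    avg_rank = avg[ord], mcm_category = as.character(tert),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Patient-level signature expression scores
#'
#' Mean over signature proteins of per-protein z-scored (across patients)
#' expression.
#'
#' @param mat proteins x patients matrix.
#' @param signature protein names.
#' @return named numeric vector per patient.
#' @export
signature_scores <- function(mat, signature) {
  m <- mat[intersect(signature, rownames(mat)), , drop = FALSE]
  if (!nrow(m)) stop("no signature proteins in matrix")
  z <- (m - rowMeans(m)) / apply(m, 1L, sd)
  colMeans(z)
}

#' Correlate signature scores with drug responses
#'
#' Per drug: Pearson correlation (with two-sided t-approximation p) between
#' the patient signature score and the on-target HSPC drug response across
#' shared patients.
#'
#' @param scores named numeric vector (patient -> signature score).
#' @param responses [score_all_drugs()] table.
#' @param readout readout to use.
#' @param min_patients minimal shared patients.
#' @return data.frame: `drug`, `n`, `r`, `p`, sorted by decreasing r.
#' @export
signature_drug_correlation <- function(scores, responses, readout = "HSPC",
                                       min_patients = 5) {
  resp <- responses[responses$readout == readout & responses$valid, ]
  rows <- list()
  for (dg in unique(resp$drug)) {
    rd <- resp[resp$drug == dg, ]
    shared <- intersect(rd$patient_id, names(scores))
    if (length(shared) < min_patients) next
    x <- scores[shared]
    y <- rd$signed_sig[match(shared, rd$patient_id)]
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- cor.test(x, y)
    rows[[dg]] <- data.frame(drug = dg, n = length(shared),
                             r = unname(ct$estimate), p = ct$p.value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$r), ]
}

#' Correlate protein levels with driver VAF within a mutation stratum
#'
#' Within the driver-stratified subcohort: per-protein Pearson correlation
#' with VAF (with p), the diagnosis-confounded ANOVA association (via
#' [protein_factor_anova()]), preranked enrichment on the correlation
#' ranking, and the significant-protein list (p < `alpha`) for network
#' assembly.
#'
#' @param mat proteins x patients matrix.
#' @param clinical clinical table.
#' @param driver `"CALR"` or `"JAK2"`.
#' @param sets gene-set list (NULL skips enrichment).
#' @param alpha significance threshold for the network protein list.
#' @param n_perm,seed enrichment parameters.
#' @return list: `table` (protein, r, p, p_adj), `anova`
#'   (diagnosis-confounded), `enrichment`, `significant` (protein ids).
#' @export
vaf_correlation <- function(mat, clinical, driver, sets = NULL, alpha = 0.01,
                            n_perm = 500, seed = 1L) {
  cl <- clinical[clinical$driver == driver, ]
  pts <- intersect(cl$patient_id, colnames(mat))
  if (length(pts) < 5) stop("driver stratum has fewer than 5 patients")
  vaf <- cl$vaf[match(pts, cl$patient_id)]
  if (sd(vaf) == 0) stop("VAF constant within stratum")
  m <- mat[, pts, drop = FALSE]
  r <- as.numeric(cor(t(m), vaf))
  n <- length(pts)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  tab <- data.frame(protein = rownames(m), r = r, p = p,
                    p_adj = p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  anova_tab <- protein_factor_anova(m, fac = vaf,
                                    confounder = factor(cl$cohort[match(pts, cl$patient_id)]))
  enr <- NULL
  if (!is.null(sets))
    enr <- gsea_preranked(stats::setNames(r, rownames(m)), sets,
                          n_perm = n_perm, seed = seed)
  list(table = tab, anova = anova_tab, enrichment = enr,
       significant = tab$protein[tab$p < alpha])
}

#' Subgroup drug differentials (homozygous CALR axes)
#'
#' Per drug: averaged difference in signed -log10 significances of the
#' oncogenic readout between a group (homozygous CALR, VAF >= 75) and two
#' references (heterozygous CALR; JAK2). Drugs with fewer than 2 patients
#' in any group are flagged NA.
#'
#' @param responses [score_all_drugs()] table.
#' @param clinical clinical table.
#' @param readout readout to compare.
#' @return data.frame per drug: `delta_vs_het_calr`, `delta_vs_jak2`, group
#'   sizes `n_hom`, `n_het`, `n_jak2`.
#' @export
subgroup_drug_differential <- function(responses, clinical,
                                       readout = "oncogenic") {
  cl <- clinical
  grp <- ifelse(cl$driver == "CALR" & cl$homozygous, "hom_calr",
         ifelse(cl$driver == "CALR", "het_calr",
         ifelse(cl$driver == "JAK2", "jak2", "other")))
  names(grp) <- cl$patient_id
  resp <- responses[responses$readout == readout & responses$valid, ]
  resp$grp <- grp[resp$patient_id]
  rows <- lapply(unique(resp$drug), function(dg) {
    sub <- resp[resp$drug == dg, ]
    mns <- tapply(sub$signed_sig, sub$grp, mean)
    ns <- table(sub$grp)
    gv <- function(g) {
      n <- ns[g]
      if (!is.na(n) && n >= 2 && g %in% names(mns)) mns[[g]] else NA_real_
    }
    hom <- gv("hom_calr"); het <- gv("het_calr"); jak <- gv("jak2")
    data.frame(drug = dg,
               delta_vs_het_calr = hom - het, delta_vs_jak2 = hom - jak,
               n_hom = sum(sub$grp == "hom_calr"),
               n_het = sum(sub$grp == "het_calr"),
               n_jak2 = sum(sub$grp == "jak2"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
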