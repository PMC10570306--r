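#' Normalize and summarize a feature table into a protein matrix
#'
#' Simplified protein-level quantification: log2-transform raw feature
#' intensities, median-center each sample to the global median, summarize
#' each protein as the median of its features. Provenance (method, centering
#' offsets) is attached as an attribute.
#'
#' @param features data.frame with columns `protein`, `feature`, `sample`,
#'   `intensity` (raw, positive).
#' @return proteins x samples log2 matrix with attribute `provenance`.
#' @export
normalize_summarize <- function(features) {
  stopifnot(all(c("protein", "feature", "sample", "intensity") %in% names(features)))
  if (any(features$intensity <= 0, na.rm = TRUE))
    stop("raw intensities must be positive")
  dt <- data.table::as.data.table(features)
  dt[, log2_int := log2(intensity)]
  med <- dt[, .(m = median(log2_int, na.rm = TRUE)), by = sample]
  global <- median(dt$log2_int, na.rm = TRUE)
  dt <- merge(dt, med, by = "sample")
  dt[, log2_int := log2_int - m + global]
  prot <- dt[, .(value = median(log2_int, na.rm = TRUE)),
             by = .(protein, sample)]
  wide <- data.table::dcast(prot, protein ~ sample, value.var = "value")
  mat <- as.matrix(wide[, -1, with = FALSE])
  rownames(mat) <- wide$protein
  attr(mat, "provenance") <- list(
    transform = "log2", normalization = "per-sample median to global median",
    summarization = "median of features",
    offsets = stats::setNames(global - med$m, med$sample))
  mat
}

#' Flag outlier samples
#'
#' Within each cell type, a sample is flagged if its median Pearson
#' correlation to the other samples of that cell type falls below
#' (cohort median - k * MAD), or its missing-value count exceeds
#' (cohort median + k * MAD). With fewer than 3 samples per cell type a
#' report is produced without flags.
#'
#' @param mat proteins x samples log2 matrix (NAs allowed).
#' @param cell_type character vector, one per sample (default: one type).
#' @param k MAD multiplier for both criteria.
#' @return data.frame per sample: `median_cor`, `n_missing`, `flag_cor`,
#'   `flag_missing`, `flag`.
#' @export
flag_outliers <- function(mat, cell_type = NULL, k = 3) {
  if (is.null(cell_type)) cell_type <- rep("all", ncol(mat))
  stopifnot(length(cell_type) == ncol(mat))
  out <- data.frame(sample = colnames(mat), cell_type = cell_type,
                    median_cor = NA_real_, n_missing = colSums(is.na(mat)),
                    flag_cor = FALSE, flag_missing = FALSE,
                    stringsAsFactors = FALSE)
  for (ct in unique(cell_type)) {
    idx <- which(cell_type == ct)
    if (length(idx) < 3L) {
      warning("fewer than 3 samples for cell type ", ct, "; no flags")
      next
    }
    cm <- suppressWarnings(cor(mat[, idx], use = "pairwise.complete.obs"))
    diag(cm) <- NA
    medc <- apply(cm, 2L, median, na.rm = TRUE)
    out$median_cor[idx] <- medc
    thr_c <- median(medc) - k * mad(medc)
    nm <- out$n_missing[idx]
    thr_m <- median(nm) + k * mad(nm)
    out$flag_cor[idx] <- medc < thr_c
    out$flag_missing[idx] <- nm > thr_m
  }
  out$flag <- out$flag_cor | out$flag_missing
  out
}

#' Group-structured missingness filter
#'
#' Retains a protein iff it is observed in at least `min_group_presence` of
#' the samples of at least one group — keeping proteins expressed
#' group-specifically while removing randomly missing ones.
#'
#' @param mat proteins x samples matrix with NAs.
#' @param groups group label per sample (no NAs).
#' @param min_group_presence presence fraction threshold (default 0.9).
#' @return filtered matrix with attribute `retained` (logical per input
#'   protein).
#' @export
filter_missingness <- function(mat, groups, min_group_presence = 0.9) {
  if (length(groups) != ncol(mat) || anyNA(groups))
    stop("every sample needs a group label")
  keep <- rep(FALSE, nrow(mat))
  for (g in unique(groups)) {
    idx <- groups == g
    pres <- rowMeans(!is.na(mat[, idx, drop = FALSE]))
    keep <- keep | pres >= min_group_presence
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "retained") <- stats::setNames(keep, rownames(mat))
  out
}

#' Left-censored minimum imputation
#'
#' Each missing value is replaced by the protein's lowest detected value
#' plus up to `noise_frac` upward uniform noise on the linear scale:
#' `log2(2^min_p * (1 + U(0, noise_frac)))`. Observed values are never
#' altered; the imputation mask is retained as an attribute.
#'
#' @param mat proteins x samples log2 matrix with NAs.
#' @param noise_frac maximal linear-scale noise fraction (default 0.05).
#' @param seed integer seed.
#' @return complete matrix with attribute `imputed` (logical mask).
#' @export
impute_left_censored <- function(mat, noise_frac = 0.05, seed = 1L) {
  if (any(rowSums(!is.na(mat)) == 0L))
    stop("protein with no observed values cannot be imputed")
  set.seed(stream_seed(seed, 7L))
  mask <- is.na(mat)
  mins <- apply(mat, 1L, min, na.rm = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) {
    u <- runif(nrow(idx), 0, noise_frac)
    mat[mask] <- mins[idx[, 1]] + log2(1 + u)
  }
  attr(mat, "imputed") <- mask
  mat
}

#' Regress out a contamination covariate
#'
#' Computes a per-sample covariate as the mean log2 level of the
#' contaminant proteins (hemoglobins A/B/D for red-blood-cell carryover in
#' density-isolated granulocytes), fits per-protein OLS of expression on the
#' covariate, and removes the fitted contribution. By default the protein's
#' mean level is preserved (residual plus intercept evaluated at the
#' covariate mean); `preserve_mean = FALSE` returns plain residuals. After
#' the transform every protein has exactly zero sample correlation with the
#' covariate.
#'
#' @param mat complete proteins x samples log2 matrix.
#' @param contaminants contaminant protein ids present in `mat`.
#' @param preserve_mean keep per-protein mean levels.
#' @return corrected matrix with attribute `covariate` (per-sample values).
#' @export
regress_contaminant <- function(mat, contaminants = c("HBA", "HBB", "HBD"),
                                preserve_mean = TRUE) {
  if (anyNA(mat)) stop("matrix must be complete (impute first)")
  miss <- setdiff(contaminants, rownames(mat))
  if (length(miss)) stop("contaminant proteins absent: ", paste(miss, collapse = ", "))
  cvt <- colMeans(mat[contaminants, , drop = FALSE])
  cc <- cvt - mean(cvt)
  vc <- sum(cc^2)
  if (vc == 0) {
    warning("constant contamination covariate; returning matrix unchanged")
    out <- mat
  } else {
    slopes <- as.numeric(mat %*% cc) / vc      # per-protein OLS slope
    out <- mat - outer(slopes, cc)
    if (!preserve_mean) out <- out - rowMeans(out)
  }
  attr(out, "covariate") <- cvt
  out
}

#' Run the full proteotype processing pipeline
#'
#' Enforced order: normalize (optional, when a feature table is given) ->
#' outlier flagging -> group-structured missingness filter -> left-censored
#' imputation -> contamination regression. The order and settings are
#' recorded in the `processing` attribute.
#'
#' @param mat proteins x samples log2 matrix with NAs.
#' @param groups group label per sample.
#' @param cell_type cell-type label per sample (for outlier flagging).
#' @param contaminants contaminant proteins; NULL skips the regression.
#' @param min_group_presence,noise_frac,seed stage parameters.
#' @param drop_outliers remove flagged samples before filtering
#'   (default keeps them: the stage's contract is the report).
#' @return processed matrix with attributes `processing`, `outliers`,
#'   `retained`, `imputed`.
#' @export
process_proteome <- function(mat, groups, cell_type = NULL,
                             contaminants = c("HBA", "HBB", "HBD"),
                             min_group_presence = 0.9, noise_frac = 0.05,
                             seed = 1L, drop_outliers = FALSE) {
  ol <- flag_outliers(mat, cell_type)
  if (drop_outliers && any(ol$flag)) {
    keep <- !ol$flag
    mat <- mat[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  filt <- filter_missingness(mat, groups, min_group_presence)
  imp <- impute_left_censored(filt, noise_frac, seed)
  out <- if (!is.null(contaminants) && all(contaminants %in% rownames(imp)))
    regress_contaminant(imp, contaminants) else imp
  attr(out, "outliers") <- ol
  attr(out, "retained") <- attr(filt, "retained")
  attr(out, "imputed") <- attr(imp, "imputed")
  attr(out, "processing") <- list(
    order = c("flag_outliers", "filter_missingness", "impute_left_censored",
              "regress_contaminant"),
    min_group_presence = min_group_presence, noise_frac = noise_frac,
    contaminants = contaminants, seed = seed,
    summarization = "median (Tukey median-polish not reproduced)")
  out
}

#' Between-sample proteotype distances for subcohort pairs
#'
#' All pairwise Euclidean distances over the full processed protein vector
#' between (or within) subcohorts, self-pairs excluded, plus Student's
#' t-tests between selected distance distributions.
#'
#' @param mat complete proteins x samples matrix.
#' @param groups group label per sample.
#' @param pairs list of 2-element character vectors naming subcohort pairs,
#'   e.g. `list(c("HD","HD"), c("HD","MF-CALR"))`.
#' @param tests optional list of 2-element integer vectors indexing `pairs`
#'   to compare by t-test.
#' @return list: `distances` (data.frame pair/dist), `tests` (data.frame).
#' @export
cohort_distances <- function(mat, groups, pairs, tests = NULL) {
  d <- as.matrix(dist(t(mat)))
  res <- list()
  for (pr in pairs) {
    ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
    if (pr[1] == pr[2]) {
      if (length(ia) < 2L) stop("within-subcohort comparison needs >= 2 samples")
      sub <- d[ia, ia]
      vals <- sub[upper.tri(sub)]
    } else {
      vals <- as.vector(d[ia, ib])
    }
    res[[paste(pr, collapse = " vs ")]] <- vals
  }
  dists <- data.frame(
    pair = rep(names(res), vapply(res, length, integer(1))),
    dist = unlist(res, use.names = FALSE), stringsAsFactors = FALSE)
  tst <- NULL
  if (!is.null(tests)) {
    tst <- do.call(rbind, lapply(tests, function(ij) {
      a <- res[[ij[1]]]; b <- res[[ij[2]]]
      tt <- ttest_pooled(a, b)
      data.frame(pair_a = names(res)[ij[1]], pair_b = names(res)[ij[2]],
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }))
  }
  list(distances = dists, tests = tst)
}
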