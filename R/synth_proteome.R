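#' Simulate proteome intensity matrices with planted effects
#'
#' Generates one log2 intensity matrix (proteins x patients) per cell type
#' (granulocyte, HSPC, T-cell) from an additive model:
#' baseline + group shifts + VAF-scaled slopes + anchor-block latent loadings
#' + hemoglobin-contamination loadings + Gaussian residual. The
#' anchor-coregulated block shares one latent per-patient score across all
#' three cell types (the replicative-activity latent); the contamination
#' latent is lognormal per sample. Values below a per-protein detection
#' limit (the configured quantile of that protein's values) are censored to
#' missing, then additional values are removed completely at random. The
#' full generative truth is returned for downstream recovery tests.
#'
#' @param clinical output of [simulate_cohort()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param cell_types character vector of cell types to emit.
#' @return list with `matrices` (named list of proteins x patients log2
#'   matrices with NAs), `truth` (list: per-block description, per-patient
#'   latent scores, per-sample contamination covariates, per-protein
#'   baselines, censoring counts).
#' @export
simulate_proteomes <- function(clinical, config, seed,
                               cell_types = c("granulocyte", "HSPC", "T-cell")) {
  stopifnot(inherits(config, "sim_config"), nrow(clinical) > 0)
  proteins <- protein_universe(config$n_proteins)
  for (b in config$blocks)
    if (!all(b$proteins %in% proteins))
      stop("block references proteins outside the universe")
  set.seed(stream_seed(seed, 2L))
  n <- nrow(clinical)
  baseline <- rnorm(config$n_proteins, config$baseline_mean, config$baseline_sd)
  names(baseline) <- proteins

  # shared latents: one replicative score per patient (all cell types),
  # one contamination level per sample (cell type specific)
  anchor_latent <- rnorm(n, 0, 1)
  names(anchor_latent) <- clinical$patient_id

  truth <- list(baseline = baseline, anchor_latent = anchor_latent,
                blocks = config$blocks, contamination = list(),
                censored = list())
  matrices <- list()
  for (ct in cell_types) {
    x <- matrix(baseline, nrow = config$n_proteins, ncol = n,
                dimnames = list(proteins, clinical$patient_id))
    h <- rlnorm(n, 0, 0.5)  # contamination latent, centred for the model
    hc <- h - mean(h)
    truth$contamination[[ct]] <- stats::setNames(h, clinical$patient_id)
    for (b in config$blocks) {
      ridx <- match(b$proteins, proteins)
      if (b$kind == "group_discriminative") {
        shift <- unlist(b$effects)[clinical$group]
        shift[is.na(shift)] <- 0
        x[ridx, ] <- x[ridx, ] + rep(shift, each = length(ridx))
      } else if (b$kind == "vaf_scaled") {
        slope <- as.numeric(b$effects)
        x[ridx, ] <- x[ridx, ] + slope * rep(clinical$vaf, each = length(ridx))
      } else if (b$kind == "anchor_coregulated") {
        load <- rep_len(b$loading, length(ridx))
        x[ridx, ] <- x[ridx, ] +
          outer(load, b$latent_sd * anchor_latent[clinical$patient_id])
      } else if (b$kind == "contaminant_loading") {
        load <- rep_len(b$loading, length(ridx))
        x[ridx, ] <- x[ridx, ] + outer(load, hc)
      }
    }
    if (config$sigma_resid > 0)
      x <- x + matrix(rnorm(length(x), 0, config$sigma_resid), nrow = nrow(x))

    # left-censoring at the per-protein empirical quantile, then MCAR
    n_cens <- 0L
    if (config$detect_quantile > 0) {
      lim <- apply(x, 1L, quantile, probs = config$detect_quantile,
                   names = FALSE)
      cens <- x < lim
      n_cens <- sum(cens)
      x[cens] <- NA_real_
    }
    if (config$mcar_rate > 0) {
      obs <- which(!is.na(x))
      drop <- obs[runif(length(obs)) < config$mcar_rate]
      x[drop] <- NA_real_
    }
    truth$censored[[ct]] <- n_cens
    matrices[[ct]] <- x
  }
  list(matrices = matrices, truth = truth)
}
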