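#' Default ex vivo drug library for simulated plates
#'
#' Small library emulating a clinical-grade screening collection: small
#' molecules are screened in duplicate at 1 and 10 uM against DMSO controls,
#' biologics in triplicate at 0.1, 1 and 10 ug/ml against PBS controls, and
#' antibodies against isotype controls.
#'
#' @param n_small,n_biologic,n_antibody drug counts per modality.
#' @return data.frame with columns `drug`, `class`, `modality`,
#'   `control_type`, `concentrations` (list column), `replicates`.
#' @export
default_drug_library <- function(n_small = 16, n_biologic = 2, n_antibody = 2) {
  classes <- c("JAKi", "BETi", "HDACi", "BCL2i", "proteasome", "topoisomerase",
               "MEKi", "PI3Ki")
  small <- data.frame(
    drug = sprintf("sm%02d", seq_len(n_small)),
    class = rep_len(classes, n_small),
    modality = rep("small_molecule", n_small),
    control_type = rep("DMSO", n_small),
    replicates = rep(2L, n_small), stringsAsFactors = FALSE)
  bio <- data.frame(
    drug = sprintf("bio%02d", seq_len(n_biologic)),
    class = rep("cytokine", n_biologic),
    modality = rep("biologic", n_biologic),
    control_type = rep("PBS", n_biologic),
    replicates = rep(3L, n_biologic), stringsAsFactors = FALSE)
  ab <- data.frame(
    drug = sprintf("ab%02d", seq_len(n_antibody)),
    class = rep("antibody", n_antibody),
    modality = rep("antibody", n_antibody),
    control_type = rep("isotype", n_antibody),
    replicates = rep(3L, n_antibody), stringsAsFactors = FALSE)
  lib <- rbind(small, bio, ab)
  if (nrow(lib) == 0L) stop("drug library is empty")
  lib$concentrations <- lapply(lib$modality, function(m)
    if (m == "small_molecule") c(1, 10) else c(0.1, 1, 10))
  lib
}

#' Planted effect block for the proteome generator
#'
#' @param kind one of `"group_discriminative"`, `"vaf_scaled"`,
#'   `"anchor_coregulated"`, `"contaminant_loading"`.
#' @param proteins member protein identifiers.
#' @param effects named numeric of log2 shifts per clinical group
#'   (`group_discriminative`), or a single slope in log2 units per VAF
#'   percent (`vaf_scaled`).
#' @param loading numeric loading(s) on the block latent
#'   (`anchor_coregulated` / `contaminant_loading`).
#' @param anchors optional anchor protein names contained in `proteins`
#'   (e.g. `c("MCM4", "MCM7")`).
#' @param latent_sd standard deviation of the per-patient latent score.
#' @return an `effect_block` list.
#' @export
effect_block <- function(kind = c("group_discriminative", "vaf_scaled",
                                  "anchor_coregulated", "contaminant_loading"),
                         proteins, effects = NULL, loading = 1,
                         anchors = NULL, latent_sd = 1) {
  kind <- match.arg(kind)
  stopifnot(length(proteins) >= 1, all(is.finite(loading)))
  if (!is.null(effects) && !all(is.finite(unlist(effects))))
    stop("effect sizes must be finite")
  if (!is.null(anchors) && !all(anchors %in% proteins))
    stop("anchors must be members of the block")
  structure(list(kind = kind, proteins = as.character(proteins),
                 effects = effects, loading = loading, anchors = anchors,
                 latent_sd = latent_sd),
            class = "effect_block")
}

#' Simulation configuration for a synthetic MPN study
#'
#' Bundles the cohort design (patients per disease-by-driver group), the
#' proteome generative model (baselines, planted effect blocks, residual
#' noise, left-censoring and MCAR missingness), and the pharmacoscopy plate
#' design (drug library, replicates, cells per well, cell-type composition
#' ranges, per-channel lognormal intensity parameters, planted drug
#' effects).
#'
#' @param n_per_group named counts for the five groups HD, ET-CALR, ET-JAK2,
#'   MF-CALR, MF-JAK2.
#' @param n_proteins proteins per cell-type matrix.
#' @param blocks list of [effect_block()] objects.
#' @param drug_library see [default_drug_library()].
#' @param drug_effects data.frame of planted per-drug survival multipliers
#'   with columns `drug`, `readout` (`"HSPC"` or `"oncogenic"`), `survival`
#'   in (0, 1], and optional `restrict` (`"all"`, `"hom_calr"`,
#'   `"mf_calr"`, `"mf_jak2"`); NULL plants no effects.
#' @param cells_per_well mean seeded cells per well (the screening default
#'   of 10,000 matches a 384-well pharmacoscopy plate; tests use fewer).
#' @param n_control_wells vehicle-control wells per control type.
#' @param hspc_range range of per-patient HSPC fractions (uniform on log
#'   scale).
#' @param n_low_hspc number of patients planted below the 0.3% HSPC QC
#'   threshold.
#' @param homozygous_frac fraction of MF-CALR patients drawn homozygous
#'   (VAF >= 75).
#' @param sigma_resid residual log2 SD of the proteome model.
#' @param detect_quantile per-protein left-censoring quantile.
#' @param mcar_rate additional missing-completely-at-random rate.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param onco_threshold ground-truth intensity threshold defining
#'   marker-positive cells (placed between the T-cell and HSPC/monocyte
#'   intensity modes).
#' @param channel_sdlog lognormal sdlog shared by all channels.
#' @param viable_rate baseline fraction of viable cells per well.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_per_group = c(HD = 8, `ET-CALR` = 8, `ET-JAK2` = 8,
                                       `MF-CALR` = 8, `MF-JAK2` = 8),
                       n_proteins = 1000,
                       blocks = list(),
                       drug_library = default_drug_library(),
                       drug_effects = NULL,
                       cells_per_well = 10000,
                       n_control_wells = 8,
                       hspc_range = c(0.01, 0.08),
                       n_low_hspc = 0,
                       homozygous_frac = 0.2,
                       sigma_resid = 0.3,
                       detect_quantile = 0.05,
                       mcar_rate = 0.02,
                       baseline_mean = 20, baseline_sd = 2,
                       onco_threshold = 60,
                       channel_sdlog = 0.35,
                       viable_rate = 0.9) {
  groups <- c("HD", "ET-CALR", "ET-JAK2", "MF-CALR", "MF-JAK2")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name all five groups: ", paste(groups, collapse = ", "))
  if (any(n_per_group <= 0)) stop("group sizes must be positive")
  stopifnot(n_proteins > 0, cells_per_well > 0, n_control_wells > 0)
  for (r in c(homozygous_frac, detect_quantile, mcar_rate, viable_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (!all(c("drug", "control_type", "replicates") %in% names(drug_library)))
    stop("drug library must define drug, control_type and replicates")
  if (any(!drug_library$control_type %in% c("DMSO", "PBS", "isotype")))
    stop("every drug needs a control type in {DMSO, PBS, isotype}")
  for (b in blocks) {
    if (!inherits(b, "effect_block")) stop("blocks must be effect_block objects")
  }
  memb <- unlist(lapply(blocks, function(b)
    if (b$kind != "contaminant_loading") b$proteins else character(0)))
  contam <- unlist(lapply(blocks, function(b)
    if (b$kind == "contaminant_loading") b$proteins else character(0)))
  if (length(intersect(memb, contam)))
    stop("effect-block members collide with contaminant proteins")
  structure(list(n_per_group = n_per_group[groups], n_proteins = n_proteins,
                 blocks = blocks, drug_library = drug_library,
                 drug_effects = drug_effects,
                 cells_per_well = cells_per_well,
                 n_control_wells = n_control_wells,
                 hspc_range = hspc_range, n_low_hspc = n_low_hspc,
                 homozygous_frac = homozygous_frac,
                 sigma_resid = sigma_resid,
                 detect_quantile = detect_quantile, mcar_rate = mcar_rate,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 onco_threshold = onco_threshold,
                 channel_sdlog = channel_sdlog, viable_rate = viable_rate),
            class = "sim_config")
}

#' Default protein identifier universe
#'
#' Generic identifiers plus named anchors used across the synthetic study:
#' MCM4/MCM7 (replication licensing), hemoglobins HBA/HBB/HBD (red-blood-cell
#' contaminants).
#'
#' @param n_proteins total proteins.
#' @return character vector of length `n_proteins`.
#' @export
protein_universe <- function(n_proteins) {
  stopifnot(n_proteins >= 10)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  ids[1:5] <- c("MCM4", "MCM7", "HBA", "HBB", "HBD")
  ids
}
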