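#' Build a plate layout from a drug library
#'
#' Every drug gets `replicates` wells per concentration (duplicates of 1 and
#' 10 uM for small molecules; triplicates of 0.1/1/10 ug/ml for biologics
#' and antibodies), plus a block of vehicle-control wells per control type
#' in use. Wells carry 25-image field metadata as in a high-content screen.
#'
#' @param config a [sim_config()].
#' @return data.frame: `well`, `drug` (NA for controls), `class`,
#'   `concentration`, `role` (drug/DMSO/PBS/isotype), `control_type`,
#'   `n_images`.
#' @export
plate_layout <- function(config) {
  lib <- config$drug_library
  rows <- list()
  for (i in seq_len(nrow(lib))) {
    concs <- lib$concentrations[[i]]
    for (cc in concs) {
      for (r in seq_len(lib$replicates[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug = lib$drug[i], class = lib$class[i], concentration = cc,
          role = "drug", control_type = lib$control_type[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  layout <- do.call(rbind, rows)
  for (ct in unique(lib$control_type)) {
    layout <- rbind(layout, data.frame(
      drug = NA_character_, class = "control", concentration = NA_real_,
      role = ct, control_type = ct,
      stringsAsFactors = FALSE)[rep(1L, config$n_control_wells), ])
  }
  layout$well <- sprintf("W%03d", seq_len(nrow(layout)))
  layout$n_images <- 25L
  rownames(layout) <- NULL
  layout[, c("well", "drug", "class", "concentration", "role",
             "control_type", "n_images")]
}

# per-class lognormal meanlog parameters for the four channels + nuclear area
.channel_params <- function() {
  # rows: HSPC, T-cell, monocyte, other; dead cells handled separately
  data.frame(
    class = c("HSPC", "T-cell", "monocyte", "other"),
    nuclear = c(6, 6, 6, 6),
    lineage = c(3, 5.5, 5.5, 3),
    cd34 = c(5.5, 3, 3, 3),
    onco = c(5, 3, 5, 4),
    area = c(log(80), log(75), log(130), log(80)),
    stringsAsFactors = FALSE)
}

#' Resolve planted drug effects to a per-patient truth table
#'
#' Expands the configured `drug_effects` (per drug, readout, survival
#' multiplier, optional subcohort restriction) into one row per patient x
#' drug x readout. Patients outside a restriction get survival 1.
#' @param clinical clinical table.
#' @param config a [sim_config()].
#' @return data.frame `patient_id`, `drug`, `readout`, `survival`.
#' @export
resolve_drug_effects <- function(clinical, config) {
  lib <- config$drug_library
  grid <- expand.grid(patient_id = clinical$patient_id, drug = lib$drug,
                      readout = c("HSPC", "oncogenic"),
                      stringsAsFactors = FALSE)
  grid$survival <- 1
  de <- config$drug_effects
  if (!is.null(de)) {
    if (is.null(de$restrict)) de$restrict <- "all"
    for (i in seq_len(nrow(de))) {
      pts <- switch(de$restrict[i],
        all = clinical$patient_id,
        hom_calr = clinical$patient_id[clinical$group == "MF-CALR" &
                                         clinical$homozygous],
        mf_calr = clinical$patient_id[clinical$group == "MF-CALR"],
        mf_jak2 = clinical$patient_id[clinical$group == "MF-JAK2"],
        stop("unknown restriction: ", de$restrict[i]))
      hit <- grid$drug == de$drug[i] & grid$readout == de$readout[i] &
        grid$patient_id %in% pts
      grid$survival[hit] <- de$survival[i]
    }
  }
  grid
}

#' Simulate pharmacoscopy single-cell plates
#'
#' For each patient, draws a cell-type composition (HSPC fraction uniform on
#' the log scale over the configured range; optionally a planted subset of
#' patients below the 0.3% QC threshold), seeds `cells_per_well` cells
#' (Poisson) into every layout well, samples cell classes, viability and
#' per-channel lognormal intensities with class-specific location
#' parameters (CD3/CD14-multiplexed lineage channel high in T-cells and
#' monocytes, CD34 high in HSPCs, oncogenic marker high in HSPC/monocyte
#' and low in T-cells). In drug wells, viable cells of the targeted
#' population are thinned by the planted survival multiplier (HSPC readout:
#' viable HSPCs; oncogenic readout: viable marker-positive cells). Truth
#' labels (class, viability, marker positivity) are retained per cell.
#'
#' @param clinical clinical table.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `cells` (data.table, one row per detected cell),
#'   `layout` (plate layout), `truth` (list: per-patient composition,
#'   per-patient drug survival table, ground-truth positivity threshold).
#' @export
simulate_pharmacoscopy <- function(clinical, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  layout <- plate_layout(config)
  if (any(!config$drug_library$control_type %in% layout$role))
    stop("drug without control wells in layout")
  set.seed(stream_seed(seed, 3L))
  n_pat <- nrow(clinical)

  # patient compositions
  hr <- log(config$hspc_range)
  hspc_f <- exp(runif(n_pat, hr[1], hr[2]))
  if (config$n_low_hspc > 0) {
    low <- sample.int(n_pat, config$n_low_hspc)
    hspc_f[low] <- runif(config$n_low_hspc, 0.0005, 0.0025)
  }
  t_f <- runif(n_pat, 0.2, 0.4)
  mono_f <- runif(n_pat, 0.1, 0.25)
  comp <- cbind(HSPC = hspc_f, `T-cell` = t_f, monocyte = mono_f,
                other = pmax(1 - hspc_f - t_f - mono_f, 0.05))
  comp <- comp / rowSums(comp)
  rownames(comp) <- clinical$patient_id

  effects <- resolve_drug_effects(clinical, config)
  eff_dt <- data.table::as.data.table(effects)
  eff_wide <- data.table::dcast(eff_dt, patient_id + drug ~ readout,
                                value.var = "survival")

  # well-level grid: patients x layout wells
  wells <- data.table::as.data.table(layout)[rep(seq_len(nrow(layout)), n_pat)]
  wells[, patient_id := rep(clinical$patient_id, each = nrow(layout))]
  wells[, plate := paste0("PL_", patient_id)]
  wells[, n_cells := rpois(.N, config$cells_per_well)]

  # class counts per well (multinomial per patient composition)
  classes <- colnames(comp)
  cnt <- matrix(0L, nrow(wells), 4L, dimnames = list(NULL, classes))
  for (p in seq_len(n_pat)) {
    idx <- which(wells$patient_id == clinical$patient_id[p])
    cnt[idx, ] <- t(vapply(wells$n_cells[idx],
                           function(nc) as.integer(rmultinom(1L, nc, comp[p, ])),
                           integer(4L)))
  }

  # expand to cells
  well_rep <- rep(seq_len(nrow(wells)), times = rowSums(cnt))
  cell_class <- unlist(lapply(seq_len(nrow(wells)), function(i)
    rep(classes, cnt[i, ])), use.names = FALSE)
  cells <- wells[well_rep, .(patient_id, plate, well, drug, class,
                             concentration, role, control_type)]
  data.table::setnames(cells, "class", "drug_class")
  cells[, cell_class := cell_class]
  nc <- nrow(cells)
  cells[, viable := runif(nc) < config$viable_rate]

  # oncogenic channel first: marker positivity feeds the planted thinning
  pars <- .channel_params()
  pi_ <- match(cells$cell_class, pars$class)
  sdl <- config$channel_sdlog
  cells[, ch_onco := rlnorm(nc, pars$onco[pi_], sdl)]
  cells[, onco_pos := ch_onco > config$onco_threshold]

  # planted drug effects: thin viable targeted cells in drug wells, before
  # the morphology draw so that killed cells acquire dead morphology
  cells <- merge(cells, eff_wide, by = c("patient_id", "drug"),
                 all.x = TRUE, sort = FALSE)
  cells[is.na(HSPC), HSPC := 1]
  cells[is.na(oncogenic), oncogenic := 1]
  u1 <- runif(nc); u2 <- runif(nc)
  cells[role == "drug" & viable & cell_class == "HSPC" & u1 > HSPC,
        viable := FALSE]
  cells[role == "drug" & viable & onco_pos & u2 > oncogenic, viable := FALSE]
  cells[, c("HSPC", "oncogenic") := NULL]

  # remaining channels; viability drives nuclear morphology
  pi_ <- match(cells$cell_class, pars$class)
  cells[, ch_nuclear := rlnorm(nc, ifelse(viable, pars$nuclear[pi_], 5.2), sdl)]
  cells[, ch_lineage := rlnorm(nc, pars$lineage[pi_], sdl)]
  cells[, ch_cd34 := rlnorm(nc, pars$cd34[pi_], sdl)]
  cells[, nuclear_area := rlnorm(nc, ifelse(viable, pars$area[pi_], log(35)), 0.25)]
  data.table::setnames(cells,
                       c("cell_class", "viable", "onco_pos"),
                       c("true_class", "true_viable", "true_onco_pos"))

  list(cells = cells[], layout = layout,
       truth = list(composition = comp, drug_effects = effects,
                    onco_threshold = config$onco_threshold))
}
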