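#' Simulate a clinical annotation table
#'
#' One row per patient across the five disease-by-driver groups. Healthy
#' donors carry no driver mutation and VAF 0; heterozygous patients draw
#' VAF from U(20, 60); a configured fraction of MF-CALR patients is drawn
#' homozygous with VAF from U(75, 100). A patient is flagged homozygous iff
#' VAF >= 75. Peripheral-blood blast percentages are elevated in MF, age and
#' sex are drawn to emulate an age/sex-matched cohort.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (all draws derive from it).
#' @return data.frame: `patient_id`, `group`, `cohort` (HD/ET/MF), `driver`
#'   (CALR/JAK2/none), `vaf` (percent), `homozygous`, `pb_blasts`, `age`,
#'   `sex`, `treated`.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(seed, 1L))
  npg <- config$n_per_group
  group <- rep(names(npg), npg)
  n <- length(group)
  cohort <- sub("-.*", "", group)
  driver <- ifelse(cohort == "HD", "none", sub(".*-", "", group))
  vaf <- numeric(n)
  het <- driver != "none"
  vaf[het] <- runif(sum(het), 20, 60)
  mfcalr <- which(group == "MF-CALR")
  n_hom <- rbinom(1L, length(mfcalr), config$homozygous_frac)
  hom_idx <- if (n_hom > 0) sample(mfcalr, n_hom) else integer(0)
  vaf[hom_idx] <- runif(length(hom_idx), 75, 100)
  pb <- ifelse(cohort == "MF", pmin(rlnorm(n, log(2), 0.8), 20),
               ifelse(cohort == "ET", pmin(rlnorm(n, log(0.5), 0.6), 5), 0))
  data.frame(
    patient_id = sprintf("PT%03d", seq_len(n)),
    group = group, cohort = cohort, driver = driver,
    vaf = round(vaf, 1), homozygous = vaf >= 75,
    pb_blasts = round(pb, 2),
    age = round(runif(n, 45, 80)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    treated = cohort != "HD" & runif(n) < 0.5,
    stringsAsFactors = FALSE)
}
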