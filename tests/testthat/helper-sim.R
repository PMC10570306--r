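# shared synthetic fixtures, built once per test run and memoized
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small cohort config with one planted drug effect, used across tests
small_screen_config <- function(...) {
  sim_config(
    n_per_group = c(HD = 2, `ET-CALR` = 2, `ET-JAK2` = 2,
                    `MF-CALR` = 3, `MF-JAK2` = 3),
    n_proteins = 120, cells_per_well = 1000,
    drug_library = default_drug_library(4, 1, 1),
    hspc_range = c(0.02, 0.06),
    ...)
}

# screen with a planted HSPC survival effect on drug sm01
small_screen <- function() fixture("small_screen", function() {
  cfg <- small_screen_config(
    drug_effects = data.frame(drug = "sm01", readout = "HSPC",
                              survival = 0.5, stringsAsFactors = FALSE))
  cl <- simulate_cohort(cfg, 7)
  ph <- simulate_pharmacoscopy(cl, cfg, 7)
  gated <- classify_and_gate(ph$cells, use_truth = TRUE)
  summ <- summarize_wells(gated)
  list(config = cfg, clinical = cl, pharm = ph, gated = gated, summ = summ)
})

# three-direction discriminative proteome structure (disease-general,
# diagnosis-specific and mutation-specific shifts over 5 proteins each)
disc_blocks <- function(universe, amp = 2) {
  b1 <- universe[21:25]; b2 <- universe[26:30]; b3 <- universe[31:35]
  list(
    effect_block("group_discriminative", b1,
                 effects = c(HD = 0, `ET-CALR` = amp, `ET-JAK2` = amp,
                             `MF-CALR` = amp, `MF-JAK2` = amp)),
    effect_block("group_discriminative", b2,
                 effects = c(HD = 0, `ET-CALR` = 0, `ET-JAK2` = 0,
                             `MF-CALR` = amp, `MF-JAK2` = amp)),
    effect_block("group_discriminative", b3,
                 effects = c(HD = 0, `ET-CALR` = amp, `ET-JAK2` = 0,
                             `MF-CALR` = amp, `MF-JAK2` = 0)))
}
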