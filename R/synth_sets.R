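#' Simulate gene sets with planted signal sets and matched decoys
#'
#' Planted sets are the members of each configured effect block; for each a
#' decoy set of the same size is drawn without replacement from proteins in
#' no block, plus additional decoy sets to reach `n_decoys`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_decoys total decoy sets.
#' @return named list of character vectors (a GeneSetCollection); planted
#'   sets are named `set_<kind>_<i>`, decoys `decoy_<j>`.
#' @export
simulate_genesets <- function(config, seed, n_decoys = 10) {
  set.seed(stream_seed(seed, 4L))
  proteins <- protein_universe(config$n_proteins)
  blocks <- config$blocks
  in_block <- unique(unlist(lapply(blocks, `[[`, "proteins")))
  free <- setdiff(proteins, in_block)
  sets <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    sets[[sprintf("set_%s_%d", b$kind, i)]] <- b$proteins
  }
  sizes <- vapply(blocks, function(b) length(b$proteins), integer(1))
  decoy_sizes <- c(sizes, rep(pmax(round(mean(c(sizes, 10))), 5),
                              max(0, n_decoys - length(sizes))))
  decoy_sizes <- head(decoy_sizes, n_decoys)
  for (j in seq_along(decoy_sizes)) {
    sets[[sprintf("decoy_%d", j)]] <- sample(free, min(decoy_sizes[j], length(free)))
  }
  sets
}

#' Simulate a protein-protein interaction edge list
#'
#' Plants high-confidence edges (scores drawn above the 0.7 interaction
#' threshold) among the members of co-regulated blocks (anchor-coregulated,
#' vaf-scaled and group-discriminative kinds), and decoy edges between
#' random non-block protein pairs with scores below the threshold.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_decoy_edges number of decoy edges.
#' @param edges_per_block planted edges sampled per block (capped at the
#'   number of distinct pairs).
#' @return data.frame `protein_a`, `protein_b`, `score`, `planted`.
#' @export
simulate_interactions <- function(config, seed, n_decoy_edges = 200,
                                  edges_per_block = 60) {
  set.seed(stream_seed(seed, 5L))
  proteins <- protein_universe(config$n_proteins)
  in_block <- unique(unlist(lapply(config$blocks, `[[`, "proteins")))
  free <- setdiff(proteins, in_block)
  out <- list()
  for (b in config$blocks) {
    if (b$kind == "contaminant_loading" || length(b$proteins) < 2) next
    pairs <- t(combn(b$proteins, 2L))
    k <- min(edges_per_block, nrow(pairs))
    pick <- pairs[sample.int(nrow(pairs), k), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      protein_a = pick[, 1], protein_b = pick[, 2],
      score = runif(k, 0.75, 0.99), planted = TRUE,
      stringsAsFactors = FALSE)
  }
  if (n_decoy_edges > 0 && length(free) >= 2) {
    a <- sample(free, n_decoy_edges, replace = TRUE)
    b <- sample(free, n_decoy_edges, replace = TRUE)
    keep <- a != b
    out[[length(out) + 1L]] <- data.frame(
      protein_a = a[keep], protein_b = b[keep],
      score = runif(sum(keep), 0.05, 0.65), planted = FALSE,
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  edges
}

#' Write a full synthetic study to a directory
#'
#' Emits the standard file interface of the pipeline: `clinical.tsv`,
#' `cells.tsv`, `plate_layout.tsv`, `proteome_<celltype>.tsv`, `sets.gmt`,
#' `edges.tsv` and a machine-readable `truth.json` describing every planted
#' effect. Identical config + seed produce identical files.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the in-memory objects.
#' @export
simulate_study <- function(config, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clinical <- simulate_cohort(config, seed)
  prot <- simulate_proteomes(clinical, config, seed)
  ph <- simulate_pharmacoscopy(clinical, config, seed)
  sets <- simulate_genesets(config, seed)
  edges <- simulate_interactions(config, seed)

  data.table::fwrite(clinical, file.path(dir, "clinical.tsv"), sep = "\t")
  data.table::fwrite(ph$cells, file.path(dir, "cells.tsv"), sep = "\t")
  data.table::fwrite(ph$layout, file.path(dir, "plate_layout.tsv"), sep = "\t")
  for (ct in names(prot$matrices)) {
    fn <- sprintf("proteome_%s.tsv", gsub("[^A-Za-z0-9]", "", ct))
    write_intensity_matrix(prot$matrices[[ct]], file.path(dir, fn))
  }
  write_gmt(sets, file.path(dir, "sets.gmt"))
  data.table::fwrite(edges, file.path(dir, "edges.tsv"), sep = "\t")

  truth <- list(
    seed = seed,
    blocks = lapply(config$blocks, unclass),
    anchor_latent = as.list(prot$truth$anchor_latent),
    contamination = lapply(prot$truth$contamination, as.list),
    drug_effects = ph$truth$drug_effects,
    composition = as.data.frame(ph$truth$composition),
    onco_threshold = ph$truth$onco_threshold)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(clinical = clinical, proteomes = prot, pharmacoscopy = ph,
                 sets = sets, edges = edges))
}
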