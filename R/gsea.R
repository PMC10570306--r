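#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum enrichment score of a set within a ranked statistic vector.
#' Hits increment by |stat|^weight normalized over the set, misses decrement
#' by 1/(N - Nh); the ES is the deviation of maximal absolute value.
#'
#' @param stats_sorted numeric statistics sorted in decreasing rank order.
#' @param hit logical vector marking set members along the ranking.
#' @param weight weighting exponent (0 = classic KS).
#' @return the enrichment score in [-1, 1].
#' @export
gsea_es <- function(stats_sorted, hit, weight = 1) {
  nh <- sum(hit)
  n <- length(stats_sorted)
  if (nh == 0L || nh == n) stop("set must be a strict non-empty subset")
  w <- abs(stats_sorted)^weight
  inc <- numeric(n)
  sw <- sum(w[hit])
  inc[hit] <- if (sw > 0) w[hit] / sw else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# deterministic ranking: decreasing statistic, ties by |stat| then name
.rank_stats <- function(stats) {
  ord <- order(-stats, -abs(stats), names(stats), method = "radix")
  stats[ord]
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Standard weighted-KS running-sum enrichment on a preranked statistic
#' vector. The null is gene-label permutation preserving set size; the
#' normalized enrichment score divides the observed ES by the mean |ES| of
#' null draws of matching sign, and the permutation p-value is the
#' fraction of same-sign null draws at least as extreme (with a +1
#' pseudo-count, so p >= 1/(n_perm + 1)). BH adjustment is applied across
#' sets.
#'
#' @param stats named numeric vector (protein -> ranking statistic).
#' @param sets named list of character vectors.
#' @param n_perm permutations per set size.
#' @param weight weighting exponent.
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe; sets outside are skipped with a warning.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `p_adj`,
#'   `direction`, `leading_edge` (comma-separated members).
#' @export
gsea_preranked <- function(stats, sets, n_perm = 1000, weight = 1,
                           seed = 1L, min_size = 5, max_size = 500) {
  stopifnot(!is.null(names(stats)), length(stats) >= 3)
  set.seed(stream_seed(seed, 8L))
  ss <- .rank_stats(stats)
  universe <- names(ss)
  n <- length(ss)

  sizes <- integer(0)
  kept <- list()
  for (nm in names(sets)) {
    mem <- intersect(sets[[nm]], universe)
    if (length(mem) < max(min_size, 1L) || length(mem) > min(max_size, n - 1L)) {
      warning("set skipped (size out of bounds or empty intersection): ", nm)
      next
    }
    kept[[nm]] <- mem
    sizes <- c(sizes, length(mem))
  }
  if (!length(kept))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), p_adj = numeric(0),
                      direction = character(0), leading_edge = character(0)))

  # shared null ES per distinct set size
  null_by_size <- list()
  for (k in unique(sizes)) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, k)] <- TRUE
      gsea_es(ss, hit, weight)
    }, numeric(1))
  }

  rows <- lapply(names(kept), function(nm) {
    mem <- kept[[nm]]
    hit <- universe %in% mem
    es <- gsea_es(ss, hit, weight)
    nulls <- null_by_size[[as.character(sum(hit))]]
    same <- nulls[sign(nulls) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    # leading edge: members at or before the ES extremum
    w <- abs(ss)^weight
    inc <- numeric(n); sw <- sum(w[hit])
    inc[hit] <- if (sw > 0) w[hit] / sw else 1 / sum(hit)
    inc[!hit] <- -1 / (n - sum(hit))
    rs <- cumsum(inc)
    peak <- which.max(abs(rs))
    le <- if (es >= 0) universe[seq_len(peak)][hit[seq_len(peak)]]
          else universe[peak:n][hit[peak:n]]
    data.frame(set = nm, size = sum(hit), es = es, nes = nes, p = p,
               direction = if (es >= 0) "positive" else "negative",
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out[, c("set", "size", "es", "nes", "p", "p_adj", "direction", "leading_edge")]
}

#' Exhaustive enumeration p-value for small GSEA problems
#'
#' Enumerates every possible placement of a set of size k in a universe of
#' size n (all `choose(n, k)` subsets), computes the ES distribution, and
#' returns the same-sign tail probability for an observed set. Used as an
#' independent oracle for the permutation p-value on toy problems.
#'
#' @param stats named numeric vector.
#' @param set member names.
#' @param weight weighting exponent.
#' @return list: `es` observed, `p_exact`, `es_all` (full distribution).
#' @export
gsea_enumerate <- function(stats, set, weight = 1) {
  ss <- .rank_stats(stats)
  universe <- names(ss)
  n <- length(ss); k <- length(intersect(set, universe))
  stopifnot(k >= 1, k < n)
  hit_obs <- universe %in% set
  es_obs <- gsea_es(ss, hit_obs, weight)
  combs <- combn(n, k)
  es_all <- apply(combs, 2L, function(ix) {
    hit <- logical(n); hit[ix] <- TRUE
    gsea_es(ss, hit, weight)
  })
  same <- es_all[sign(es_all) == sign(es_obs)]
  p <- sum(abs(same) >= abs(es_obs)) / length(same)
  list(es = es_obs, p_exact = p, es_all = es_all)
}
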