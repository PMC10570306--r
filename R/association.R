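#' Per-protein ANOVA against a clinical factor with optional confounder
#'
#' For every protein, fits the linear model `x ~ confounder + factor` (or
#' `x ~ factor`) and tests the factor term by the nested-model F-test. The
#' shared design is decomposed once, so thousands of proteins are tested by
#' matrix algebra. The sign is the direction of the factor effect: for a
#' two-level factor, positive when the first level is higher; for a
#' continuous factor, the sign of the slope. BH adjustment across proteins.
#'
#' @param mat complete proteins x samples matrix.
#' @param fac factor (2+ levels) or numeric vector, one value per sample.
#' @param confounder optional factor/numeric confounder.
#' @return data.frame per protein: `protein`, `statistic` (F), `p`, `p_adj`,
#'   `sign`, `signed_sig`.
#' @export
protein_factor_anova <- function(mat, fac, confounder = NULL) {
  if (is.character(fac)) fac <- factor(fac)
  if (is.factor(fac) && nlevels(droplevels(fac)) < 2)
    stop("factor is constant")
  if (is.numeric(fac) && var(fac) == 0) stop("factor is constant")
  n <- ncol(mat)
  if (length(fac) != n) stop("factor length must match sample count")
  df_full <- if (is.null(confounder)) data.frame(fac = fac)
             else data.frame(fac = fac, conf = confounder)
  X_full <- model.matrix(if (is.null(confounder)) ~fac else ~conf + fac,
                         df_full)
  X_red <- model.matrix(if (is.null(confounder)) ~1 else ~conf, df_full)
  qr_full <- qr(X_full); qr_red <- qr(X_red)
  collinear <- qr_full$rank < ncol(X_full)
  if (collinear && qr_full$rank == qr_red$rank) {
    warning("factor collinear with confounder; p set to NA")
    return(data.frame(protein = rownames(mat), statistic = NA_real_,
                      p = NA_real_, p_adj = NA_real_, sign = NA_real_,
                      signed_sig = NA_real_, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  Y <- t(mat)                                   # samples x proteins
  rss <- function(qrx) {
    Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    colSums(Y^2) - colSums((crossprod(Q, Y))^2)
  }
  rss_f <- rss(qr_full); rss_r <- rss(qr_red)
  df1 <- qr_full$rank - qr_red$rank
  df2 <- n - qr_full$rank
  if (df1 < 1 || df2 < 1) stop("insufficient degrees of freedom")
  Fstat <- pmax(rss_r - rss_f, 0) / df1 / (rss_f / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  p[rss_f == 0 & rss_r == rss_f] <- 1

  # effect direction
  if (is.factor(fac)) {
    lv <- levels(droplevels(fac))
    if (length(lv) == 2) {
      d <- rowMeans(mat[, fac == lv[1], drop = FALSE]) -
        rowMeans(mat[, fac == lv[2], drop = FALSE])
      sgn <- sign(d)
    } else sgn <- rep(1, nrow(mat))
  } else {
    fc <- fac - mean(fac)
    sgn <- sign(as.numeric(mat %*% fc))
  }
  out <- data.frame(protein = rownames(mat), statistic = Fstat, p = p,
                    p_adj = p.adjust(p, "BH"), sign = sgn,
                    signed_sig = signed_significance(p, sgn),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (collinear) {
    warning("factor collinear with confounder; p set to NA")
    out$p <- out$p_adj <- out$signed_sig <- NA_real_
  }
  out
}

#' Two-group differential expression (volcano table)
#'
#' Per protein: mean difference (log2FC, group A minus group B), two-sided
#' pooled Student's t, p and signed -log10 p.
#'
#' @param mat proteins x samples matrix.
#' @param groups group label per sample.
#' @param level_a,level_b labels of the two groups to compare.
#' @return data.frame: `protein`, `log2fc`, `t`, `p`, `p_adj`, `signed_sig`.
#' @export
differential_t <- function(mat, groups, level_a, level_b) {
  ia <- which(groups == level_a); ib <- which(groups == level_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples")
  tab <- row_ttest(mat, ia, ib)
  names(tab)[1] <- "protein"
  tab$p_adj <- p.adjust(tab$p, "BH")
  tab[, c("protein", "log2fc", "t", "p", "p_adj", "signed_sig")]
}

#' Assemble a factor-protein-pathway association network
#'
#' Per factor: protein nodes are the top `top_k` proteins by adjusted
#' ANOVA p among those below `alpha_adj`; pathway nodes are sets with
#' adjusted enrichment p below `pathway_alpha_adj`. Protein-protein
#' interaction edges are restricted to included protein nodes with score
#' above `score_min`. Factor-protein and factor-pathway edge weights are
#' signed -log10 significances.
#'
#' @param assoc named list (factor -> [protein_factor_anova()] table).
#' @param enrich named list (factor -> [gsea_preranked()] table), optional.
#' @param edges data.frame `protein_a`, `protein_b`, `score`, optional.
#' @param top_k,alpha_adj,pathway_alpha_adj,score_min thresholds.
#' @return list of data.frames `nodes` (id, type) and `edges`
#'   (from, to, type, weight).
#' @export
build_network <- function(assoc, enrich = NULL, edges = NULL, top_k = 20,
                          alpha_adj = 0.001, pathway_alpha_adj = 0.05,
                          score_min = 0.7) {
  nodes <- list(); elist <- list()
  for (f in names(assoc)) {
    a <- assoc[[f]]
    a <- a[!is.na(a$p_adj) & a$p_adj < alpha_adj, ]
    a <- a[order(a$p_adj, a$p, a$protein), ]
    a <- head(a, top_k)
    if (nrow(a)) {
      nodes[[length(nodes) + 1L]] <- data.frame(id = a$protein, type = "protein")
      elist[[length(elist) + 1L]] <- data.frame(
        from = f, to = a$protein, type = "factor-protein",
        weight = a$signed_sig, stringsAsFactors = FALSE)
    }
    if (!is.null(enrich) && !is.null(enrich[[f]])) {
      e <- enrich[[f]]
      e <- e[e$p_adj < pathway_alpha_adj, ]
      if (nrow(e)) {
        nodes[[length(nodes) + 1L]] <- data.frame(id = e$set, type = "pathway")
        elist[[length(elist) + 1L]] <- data.frame(
          from = f, to = e$set, type = "factor-pathway",
          weight = signed_significance(e$p, ifelse(e$es >= 0, 1, -1)),
          stringsAsFactors = FALSE)
      }
    }
    nodes[[length(nodes) + 1L]] <- data.frame(id = f, type = "factor")
  }
  node_df <- unique(do.call(rbind, nodes))
  prot_nodes <- node_df$id[node_df$type == "protein"]
  if (!is.null(edges) && length(prot_nodes)) {
    pp <- edges[edges$score > score_min &
                  edges$protein_a %in% prot_nodes &
                  edges$protein_b %in% prot_nodes, , drop = FALSE]
    if (nrow(pp))
      elist[[length(elist) + 1L]] <- data.frame(
        from = pp$protein_a, to = pp$protein_b, type = "protein-protein",
        weight = pp$score, stringsAsFactors = FALSE)
  }
  edge_df <- if (length(elist)) do.call(rbind, elist)
             else data.frame(from = character(0), to = character(0),
                             type = character(0), weight = numeric(0))
  if (nrow(node_df) <= length(assoc))
    warning("no qualifying protein or pathway nodes; empty network")
  rownames(node_df) <- rownames(edge_df) <- NULL
  list(nodes = node_df, edges = edge_df)
}
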