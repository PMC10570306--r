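#' Derive a per-stream RNG seed from a root seed
#'
#' All stochastic stages of the pipeline draw their seeds from one root seed
#' through this deterministic scheme, so that a single integer reproduces an
#' entire simulated study while the individual stages (cohort, proteomes,
#' plates, gene sets, imputation, RFE runs) remain independently replayable.
#'
#' @param seed root integer seed.
#' @param stream small non-negative integer identifying the consumer stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(seed) * 48271 + stream * 16807 + 1) %% 2147483647)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Plain two-sided Student's t on two vectors with the pooled variance
#' estimate. Degenerate inputs follow fixed rules: if both groups have zero
#' variance and equal means the p-value is 1; if variances are zero but the
#' means differ the p-value underflows to the smallest representable positive
#' double rather than NaN.
#'
#' @param x,y numeric vectors (each length >= 1; a t-statistic requires
#'   `length(x) + length(y) >= 3`).
#' @return list with elements `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
ttest_pooled <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  mx <- mean(x); my <- mean(y)
  df <- nx + ny - 2L
  if (df < 1L) return(list(t = NA_real_, df = df, p = NA_real_, mean_x = mx, mean_y = my))
  sp2 <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    if (mx == my) return(list(t = 0, df = df, p = 1, mean_x = mx, mean_y = my))
    return(list(t = sign(mx - my) * Inf, df = df, p = .Machine$double.xmin,
                mean_x = mx, mean_y = my))
  }
  tt <- (mx - my) / se
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), mean_x = mx, mean_y = my)
}

#' Signed significance
#'
#' `-log10(p)` signed by the direction of the effect: positive for on-target
#' (depletion / positive relative reduction), negative for off-target.
#' p-values are floored at 1e-300 before the log so the result stays finite.
#'
#' @param p p-value(s) in (0, 1].
#' @param direction sign carrier; only its sign is used (0 maps to 0).
#' @return numeric signed significance.
#' @export
signed_significance <- function(p, direction) {
  sign(direction) * -log10(pmax(p, 1e-300))
}

#' Row-wise two-sample pooled t-tests on a matrix
#'
#' Vectorized Student's t per row (protein) comparing two sample groups,
#' returning mean difference (log2FC on log2 data), t, p and signed
#' significance. Missing values are dropped per row.
#'
#' @param mat numeric matrix, features x samples.
#' @param idx_a,idx_b column indices (or logical masks) of the two groups.
#' @return data.frame with columns `feature`, `log2fc`, `t`, `p`,
#'   `signed_sig` (positive = higher in group A).
#' @export
row_ttest <- function(mat, idx_a, idx_b) {
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb_ <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  ssa <- rowSums((a - ma)^2, na.rm = TRUE)
  ssb <- rowSums((b - mb)^2, na.rm = TRUE)
  df <- na_ + nb_ - 2
  sp2 <- (ssa + ssb) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / na_ + 1 / nb_))
  d <- ma - mb
  tt <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(df >= 1,
              ifelse(is.finite(tt), 2 * pt(-abs(tt), pmax(df, 1)),
                     .Machine$double.xmin),
              NA_real_)
  p[se == 0 & d == 0] <- 1
  data.frame(feature = rownames(mat), log2fc = d, t = tt, p = p,
             signed_sig = signed_significance(p, d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then members.
#'
#' @param path file path.
#' @return named list of character vectors of member identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, mem) paste(c(nm, ds, mem), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a protein intensity matrix as TSV
#'
#' Proteins as rows, samples as columns, header row of sample identifiers,
#' empty field = missing value.
#'
#' @param path file path.
#' @return numeric matrix with protein rownames.
#' @export
read_intensity_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  m
}

#' @rdname read_intensity_matrix
#' @param mat numeric matrix, proteins x samples.
#' @export
write_intensity_matrix <- function(mat, path) {
  dt <- data.table::data.table(protein = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
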