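#' Stratified index split
#'
#' Splits samples into disjoint train / validation / test partitions with
#' per-class stratification; every class is guaranteed at least one training
#' sample, and splits that lose a class from the training partition are
#' rejected.
#'
#' @param y class labels.
#' @param split fractions summing to 1 (train, validation, test).
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(y, split = c(0.7, 0.2, 0.1)) {
  stopifnot(abs(sum(split) - 1) < 1e-8)
  y <- factor(y)
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (k in levels(y)) {
    ik <- sample(which(y == k))
    n <- length(ik)
    n_tr <- max(2L, round(split[1] * n))
    n_va <- max(1L, round(split[2] * n))
    n_tr <- min(n_tr, n - 2L)
    n_va <- min(n_va, n - n_tr - 1L)
    if (n_tr < 2L || n_va < 1L || n - n_tr - n_va < 1L)
      stop("class ", k, " too small for a stratified 70/20/10 split")
    idx$train <- c(idx$train, ik[seq_len(n_tr)])
    idx$validation <- c(idx$validation, ik[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, ik[(n_tr + n_va + 1L):n])
  }
  idx
}

# ridge multinomial feature importance: sum over classes of |standardized
# coefficient|, averaged across cv folds
.rfe_importance <- function(x, y, folds, lambda = 0.05) {
  p <- ncol(x)
  imp <- numeric(p)
  sds <- apply(x, 2L, sd); sds[sds == 0] <- 1
  for (f in unique(folds)) {
    xt <- x[folds != f, , drop = FALSE]
    yt <- y[folds != f]
    fit <- glmnet::glmnet(xt, yt, family = "multinomial", alpha = 0,
                          lambda = c(0.5, lambda), standardize = TRUE)
    cf <- coef(fit, s = lambda)
    b <- vapply(cf, function(m) abs(as.numeric(m[-1, 1])), numeric(p))
    imp <- imp + rowSums(b) * sds
  }
  imp / length(unique(folds))
}

.make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ik <- sample(which(y == cl))
    fold[ik] <- rep_len(seq_len(k), length(ik))
  }
  fold
}

.fit_mlp <- function(x, y, size, decay, seed_offset = 0L) {
  yin <- nnet::class.ind(y)
  nnet::nnet(x, yin, size = size, decay = decay, softmax = TRUE,
             maxit = 1000, MaxNWts = 10000, trace = FALSE)
}

.predict_mlp <- function(fit, x, levels_) {
  pr <- predict(fit, x)
  factor(levels_[max.col(pr)], levels = levels_)
}

.f1_scores <- function(truth, pred) {
  lv <- levels(truth)
  f1 <- vapply(lv, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  wts <- as.numeric(table(truth)[lv])
  list(macro_f1 = mean(f1), weighted_f1 = sum(f1 * wts) / sum(wts))
}

#' One recursive-feature-elimination / MLP run
#'
#' A single seeded run of the signature-selection scheme: stratified
#' 70/20/10 train/validation/test split; recursive feature elimination on
#' the training set, ranking features at each step by ridge-multinomial
#' coefficient magnitudes averaged over 6 stratified CV folds and dropping
#' the lowest 10% (floor 1) until `n_features` remain; a multilayer
#' perceptron trained on the selected features with a small hyperparameter
#' grid (hidden size x weight decay) chosen on the validation split; final
#' accuracy, weighted F1 and macro F1 on the untouched test split.
#'
#' @param x samples x proteins matrix.
#' @param y class labels (5 disease-by-driver groups in the study design).
#' @param run_seed integer seed for this run.
#' @param n_features features to retain.
#' @param split train/validation/test fractions.
#' @param cv_folds folds for the elimination ranking.
#' @param elim_frac fraction of remaining features dropped per step.
#' @param grid data.frame of `size`, `decay` combinations.
#' @return list: `selected` (protein names), `test_accuracy`,
#'   `weighted_f1`, `macro_f1`, `cv_accuracy` (mean fold accuracy of a
#'   ridge classifier on the selected features), `best` (tuned
#'   hyperparameters), `indices` (the split).
#' @export
rfe_run <- function(x, y, run_seed, n_features = 30,
                    split = c(0.7, 0.2, 0.1), cv_folds = 6,
                    elim_frac = 0.1,
                    grid = expand.grid(size = c(4, 8), decay = c(0.01, 0.1))) {
  y <- factor(y)
  if (any(table(y) < 4L)) stop("every class needs >= 4 samples")
  set.seed(stream_seed(run_seed, 9L))
  idx <- stratified_split(y, split)
  xtr <- x[idx$train, , drop = FALSE]; ytr <- droplevels(y[idx$train])
  if (nlevels(ytr) < nlevels(droplevels(y)))
    stop("class lost from training split")
  keep <- seq_len(ncol(x))
  n_features <- min(n_features, ncol(x))
  folds <- .make_folds(ytr, cv_folds)
  while (length(keep) > n_features) {
    imp <- .rfe_importance(xtr[, keep, drop = FALSE], ytr, folds)
    n_drop <- max(1L, floor(elim_frac * length(keep)))
    n_drop <- min(n_drop, length(keep) - n_features)
    keep <- keep[order(imp, decreasing = TRUE)][seq_len(length(keep) - n_drop)]
  }
  sel <- colnames(x)[keep]

  # center on training statistics; variances are left untouched so that
  # high-variance (typically informative) proteins keep their weight
  mu <- colMeans(xtr[, keep, drop = FALSE])
  sc <- function(m) sweep(m[, keep, drop = FALSE], 2L, mu)
  xt <- sc(x[idx$train, , drop = FALSE])
  xv <- sc(x[idx$validation, , drop = FALSE])
  xs <- sc(x[idx$test, , drop = FALSE])
  yv <- y[idx$validation]; ys <- y[idx$test]

  best <- NULL; best_acc <- -1
  for (g in seq_len(nrow(grid))) {
    fit <- .fit_mlp(xt, ytr, grid$size[g], grid$decay[g])
    acc <- mean(.predict_mlp(fit, xv, levels(y)) == yv)
    if (acc > best_acc) { best_acc <- acc; best <- list(fit = fit, row = g) }
  }
  pred <- .predict_mlp(best$fit, xs, levels(y))
  f1 <- .f1_scores(factor(ys, levels = levels(y)), pred)

  # cross-validation score on selected features (fold-held-out ridge accuracy)
  cv_acc <- mean(vapply(unique(folds), function(f) {
    fit <- glmnet::glmnet(xt[folds != f, , drop = FALSE], ytr[folds != f],
                          family = "multinomial", alpha = 0,
                          lambda = c(0.5, 0.05))
    pr <- predict(fit, xt[folds == f, , drop = FALSE], s = 0.05,
                  type = "class")
    mean(pr == as.character(ytr[folds == f]))
  }, numeric(1)))

  list(selected = sel, test_accuracy = mean(pred == ys),
       weighted_f1 = f1$weighted_f1, macro_f1 = f1$macro_f1,
       cv_accuracy = cv_acc,
       best = grid[best$row, , drop = FALSE], indices = idx,
       run_seed = run_seed)
}

#' Repeated-RFE signature selection
#'
#' Runs [rfe_run()] `n_runs` times with seeds `base_seed + run index`,
#' aggregates per-protein selection frequencies, and emits the signature of
#' proteins selected in at least `min_freq` runs.
#'
#' @param x samples x proteins matrix.
#' @param y class labels.
#' @param n_runs number of runs (study default 100).
#' @param min_freq selection-count threshold for the signature (study
#'   default 85 of 100).
#' @param base_seed integer base seed.
#' @param ... passed to [rfe_run()].
#' @return list: `frequency` (named counts over all proteins selected at
#'   least once), `signature`, `runs` (list of run results), `scores`
#'   (data.frame of per-run test scores), `summary` (mean/sd of scores).
#' @export
select_signature <- function(x, y, n_runs = 100, min_freq = 85,
                             base_seed = 1L, ...) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  runs <- lapply(seq_len(n_runs), function(i)
    rfe_run(x, y, run_seed = base_seed + i, ...))
  sel <- unlist(lapply(runs, `[[`, "selected"))
  freq <- sort(table(sel), decreasing = TRUE)
  freq <- stats::setNames(as.integer(freq), names(freq))
  scores <- data.frame(
    run = seq_len(n_runs),
    test_accuracy = vapply(runs, `[[`, numeric(1), "test_accuracy"),
    weighted_f1 = vapply(runs, `[[`, numeric(1), "weighted_f1"),
    macro_f1 = vapply(runs, `[[`, numeric(1), "macro_f1"),
    cv_accuracy = vapply(runs, `[[`, numeric(1), "cv_accuracy"))
  list(frequency = freq,
       signature = names(freq)[freq >= min_freq],
       runs = runs, scores = scores,
       summary = data.frame(
         metric = c("test_accuracy", "weighted_f1", "macro_f1"),
         mean = c(mean(scores$test_accuracy), mean(scores$weighted_f1),
                  mean(scores$macro_f1)),
         sd = c(sd(scores$test_accuracy), sd(scores$weighted_f1),
                sd(scores$macro_f1))))
}
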