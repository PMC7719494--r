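# Wrapper feature-selection objective: stratified k-fold cross-validated
# KNN accuracy on the selected gene columns, plus a sparsity reward.

#' Construct a feature-selection dataset
#'
#' Bundles a samples-by-genes expression matrix with one class label per
#' sample. Labels are recoded to contiguous integer codes 1..K; the original
#' labels are kept as factor levels.
#'
#' @param X Numeric matrix, `n_samples x n_features`, no missing values.
#' @param y Class label vector of length `n_samples` (factor, character or
#'   integer); at least two classes.
#' @param feature_names Optional character vector of gene names; defaults to
#'   existing column names or `g1..gd`.
#' @return An object of class `fs_dataset` with elements `X`, `y` (integer
#'   codes), `classes` (original labels) and `feature_names`.
#' @export
fs_dataset <- function(X, y, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("expression matrix contains missing values", call. = FALSE)
  if (nrow(X) != length(y))
    stop("length of 'y' must equal nrow(X)", call. = FALSE)
  yf <- factor(y)
  if (nlevels(yf) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(feature_names)) feature_names <- colnames(X)
  if (is.null(feature_names)) feature_names <- paste0("g", seq_len(ncol(X)))
  stopifnot(length(feature_names) == ncol(X))
  colnames(X) <- feature_names
  structure(list(X = X, y = as.integer(yf), classes = levels(yf),
                 feature_names = feature_names),
            class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat(sprintf("fs_dataset: %d samples x %d features, %d classes (%s)\n",
              nrow(x$X), ncol(x$X), length(x$classes),
              paste(table(x$y), collapse = "/")))
  invisible(x)
}

#' Configuration for the wrapper fitness
#'
#' @param omega Weight of the sparsity reward in the fitness
#'   `Acc + omega * (1 - sf/nf)`, in \[0, 1\]. Default 0.5.
#' @param knn_k Neighbour count for the KNN classifier; must be smaller than
#'   the smallest training-fold size. Default 5.
#' @param n_folds Cross-validation fold count (>= 2). Reduced to the
#'   smallest class size, with a warning, when a class is rarer than the
#'   requested fold count. Default 10.
#' @param scale Min-max scale each feature using training-fold statistics
#'   before computing distances. Default `TRUE`.
#' @param seed Integer seed controlling fold assignment and classifier
#'   tie-breaking; evaluation is deterministic given (`seed`, data, mask).
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(omega = 0.5, knn_k = 5L, n_folds = 10L,
                           scale = TRUE, seed = 1L) {
  if (!is.numeric(omega) || omega < 0 || omega > 1)
    stop("'omega' must lie in [0, 1]", call. = FALSE)
  knn_k <- as.integer(knn_k); n_folds <- as.integer(n_folds)
  if (is.na(knn_k) || knn_k < 1L) stop("'knn_k' must be >= 1", call. = FALSE)
  if (is.na(n_folds) || n_folds < 2L)
    stop("'n_folds' must be >= 2", call. = FALSE)
  structure(list(omega = omega, knn_k = knn_k, n_folds = n_folds,
                 scale = isTRUE(scale), seed = as.integer(seed)),
            class = "fitness_config")
}

# Stratified fold assignment (list of test-index vectors), deterministic
# given cfg$seed and the label vector. Fold count is reduced to the
# smallest class size when necessary.
make_cv_folds <- function(y, cfg) {
  k <- cfg$n_folds
  min_class <- min(table(y))
  if (min_class < k) {
    warning(sprintf("reducing fold count from %d to smallest class size %d",
                    k, min_class), call. = FALSE)
    k <- max(2L, as.integer(min_class))
  }
  withr::with_seed(cfg$seed,
                   caret::createFolds(factor(y), k = k, list = TRUE,
                                      returnTrain = FALSE))
}

min_max_scale <- function(train, test) {
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant feature -> zero spread, no distance signal
  train <- sweep(sweep(train, 2L, lo), 2L, rng, "/")
  test <- sweep(sweep(test, 2L, lo), 2L, rng, "/")
  list(train = train, test = test)
}

# Precompute, per fold, the training/test matrices scaled over ALL features
# by training-fold min-max statistics. Scaling is per-column, so restricting
# to a mask commutes with it; repeated mask evaluations then reduce to
# column subsetting plus the KNN vote.
prepare_cv <- function(data, cfg, folds = NULL) {
  if (is.null(folds)) folds <- make_cv_folds(data$y, cfg)
  X <- data$X; y <- data$y
  prep <- lapply(folds, function(test_idx) {
    sc <- if (cfg$scale)
      min_max_scale(X[-test_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
    else
      list(train = X[-test_idx, , drop = FALSE],
           test = X[test_idx, , drop = FALSE])
    list(train = sc$train, test = sc$test,
         cl = factor(y[-test_idx]), y_test = y[test_idx])
  })
  min_train <- nrow(X) - max(lengths(folds))
  if (cfg$knn_k >= min_train)
    stop(sprintf("knn_k = %d must be smaller than the smallest training fold (%d)",
                 cfg$knn_k, min_train), call. = FALSE)
  list(folds = prep, n = nrow(X), seed = cfg$seed, k = cfg$knn_k)
}

knn_eval <- function(prep, sel) {
  withr::with_seed(prep$seed, {
    correct <- 0L
    for (fl in prep$folds) {
      pred <- class::knn(fl$train[, sel, drop = FALSE],
                         fl$test[, sel, drop = FALSE],
                         cl = fl$cl, k = prep$k, use.all = TRUE)
      correct <- correct + sum(as.integer(as.character(pred)) == fl$y_test)
    }
    correct / prep$n
  })
}

#' Cross-validated KNN accuracy of a feature subset
#'
#' Restricts the expression matrix to the genes flagged in `mask`, min-max
#' scales each retained gene using training-fold statistics only (no test
#' leakage), and classifies each held-out fold with a Euclidean k-nearest
#' neighbour vote under stratified cross-validation. Returns the mean
#' held-out accuracy across folds. The entire evaluation runs under a seed
#' derived from the configuration, so a given (data, mask, config) triple
#' always yields the same accuracy and the caller's random stream is
#' untouched.
#'
#' @param data An [fs_dataset()].
#' @param mask 0/1 vector of length `n_features` with at least one bit set.
#' @param cfg A [fitness_config()].
#' @param folds Optional precomputed stratified fold list, or the prepared
#'   cross-validation object an [make_fs_fitness()] closure uses internally;
#'   defaults to a fresh stratified assignment under `cfg$seed`.
#' @return Mean test accuracy in \[0, 1\].
#' @export
knn_cv_accuracy <- function(data, mask, cfg = fitness_config(), folds = NULL) {
  stopifnot(inherits(data, "fs_dataset"))
  mask <- as.integer(mask)
  if (length(mask) != ncol(data$X))
    stop("mask length must equal the number of features", call. = FALSE)
  if (sum(mask) < 1L)
    stop("mask selects no features; repair it before scoring", call. = FALSE)
  prep <- if (is.list(folds) && !is.null(folds$folds)) folds
          else prepare_cv(data, cfg, folds)
  knn_eval(prep, which(mask == 1L))
}

#' Wrapper fitness of a feature subset
#'
#' The maximized objective `Acc + omega * (1 - sf / nf)`, where `Acc` is the
#' cross-validated KNN accuracy of the masked genes, `sf` the number of
#' selected genes and `nf` the total gene count. The value lies in
#' `[0, 1 + omega]`; at the default `omega = 0.5` the analytic ceiling is
#' 1.5, approached by perfectly accurate, maximally sparse subsets. An
#' all-zero mask is repaired by setting one randomly chosen bit (drawn from
#' the current random stream) so the objective stays defined everywhere.
#'
#' @inheritParams knn_cv_accuracy
#' @return Numeric fitness with attributes `accuracy`, `mask` (the possibly
#'   repaired mask) and `n_selected`.
#' @export
fs_fitness <- function(data, mask, cfg = fitness_config(), folds = NULL) {
  mask <- as.integer(mask)
  nf <- ncol(data$X)
  stopifnot(length(mask) == nf)
  if (sum(mask) == 0L) mask[sample.int(nf, 1L)] <- 1L
  acc <- knn_cv_accuracy(data, mask, cfg, folds = folds)
  sf <- sum(mask)
  structure(acc + cfg$omega * (1 - sf / nf),
            accuracy = acc, mask = mask, n_selected = sf)
}

#' Build a position-level fitness callable for the binary optimizer
#'
#' Binds a dataset, fitness configuration and transfer function into the
#' continuous-position fitness contract of [po_optimize()]: each call
#' binarizes the position with [binarize_position()] (consuming the run's
#' random stream), repairs empty masks, and scores the mask with
#' [fs_fitness()]. Fold assignment is computed once, and accuracies are
#' cached per distinct mask, since identical masks recur heavily during a
#' run and the cross-validation dominates runtime.
#'
#' @param data An [fs_dataset()].
#' @param cfg A [fitness_config()].
#' @param transfer `"s"` (BPO-S) or `"v"` (BPO-V).
#' @return A function `position -> fitness` with the binary mask attached
#'   as `attr(value, "mask")`.
#' @export
make_fs_fitness <- function(data, cfg = fitness_config(),
                            transfer = c("s", "v")) {
  transfer <- match.arg(transfer)
  prep <- prepare_cv(data, cfg)
  nf <- ncol(data$X)
  cache <- new.env(parent = emptyenv())
  function(position) {
    stopifnot(length(position) == nf)
    mask <- binarize_position(position, kind = transfer)
    if (sum(mask) == 0L) mask[sample.int(nf, 1L)] <- 1L
    key <- paste(which(mask == 1L), collapse = ",")
    acc <- cache[[key]]
    if (is.null(acc)) {
      acc <- knn_eval(prep, which(mask == 1L))
      cache[[key]] <- acc
    }
    sf <- sum(mask)
    structure(acc + cfg$omega * (1 - sf / nf),
              accuracy = acc, mask = mask, n_selected = sf)
  }
}
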