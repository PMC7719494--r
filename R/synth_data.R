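# Synthetic gene-expression generator with planted informative genes, and
# the exhaustive subset-search oracle used to bound heuristic results on
# small feature spaces.

#' Specification for a synthetic expression dataset
#'
#' Describes a Gaussian class-shift model: a small planted set of
#' informative genes whose class-conditional means are separated by
#' `effect_size * noise_sd`, optional redundant genes (noisy copies of
#' informative ones), and pure-noise genes for the remainder.
#'
#' @param n_samples Number of samples (>= 2 per class).
#' @param n_features Total number of genes.
#' @param n_informative Number of class-informative genes.
#' @param n_classes Number of classes (>= 2). Default 2.
#' @param effect_size Class-mean shift in units of `noise_sd` (>= 0).
#'   Default 2.
#' @param noise_sd Standard deviation of the Gaussian noise (> 0).
#'   Default 1.
#' @param n_redundant Number of noisy copies of informative genes (>= 0).
#'   Default 0.
#' @param seed Integer seed; identical specs generate identical matrices.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_features, n_informative,
                           n_classes = 2L, effect_size = 2, noise_sd = 1,
                           n_redundant = 0L, seed = 1L) {
  n_samples <- as.integer(n_samples); n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  n_classes <- as.integer(n_classes); n_redundant <- as.integer(n_redundant)
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  if (n_samples < 2L * n_classes)
    stop("need at least 2 samples per class", call. = FALSE)
  if (n_informative < 0L || n_redundant < 0L ||
      n_informative + n_redundant > n_features)
    stop("'n_informative' + 'n_redundant' must not exceed 'n_features'",
         call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("'effect_size' must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be > 0", call. = FALSE)
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, n_classes = n_classes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_redundant = n_redundant, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with planted informative genes
#'
#' Class labels are balanced up to the division remainder. Every gene
#' starts as Gaussian noise; each informative gene then receives a
#' class-conditional mean offset, `effect_size * noise_sd` apart between
#' adjacent classes, with the class-to-offset assignment permuted
#' independently per gene so informative genes are not mutually redundant.
#' Redundant genes are informative genes plus fresh noise of the same
#' standard deviation.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `data` (an [fs_dataset()]), `informative`
#'   (sorted indices of the planted informative genes) and `redundant`
#'   (indices of the noisy copies).
#' @examples
#' out <- synth_expression(synthetic_spec(40, 20, 3, seed = 7))
#' out$informative
#' @export
synth_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples; d <- spec$n_features; g <- spec$n_classes
    y <- rep_len(seq_len(g), n)
    X <- matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
    planted <- sample.int(d, spec$n_informative + spec$n_redundant)
    informative <- sort(planted[seq_len(spec$n_informative)])
    redundant <- sort(planted[-seq_len(spec$n_informative)])
    shift <- spec$effect_size * spec$noise_sd
    for (f in informative) {
      offsets <- shift * (sample.int(g) - 1L)  # permuted class-to-mean map
      X[, f] <- X[, f] + offsets[y]
    }
    for (f in redundant) {
      src <- informative[sample.int(length(informative), 1L)]
      X[, f] <- X[, src] + stats::rnorm(n, sd = spec$noise_sd)
    }
    data <- fs_dataset(X, y, feature_names = sprintf("g%d", seq_len(d)))
    list(data = data, informative = informative, redundant = redundant)
  })
}

#' Exhaustive best subset (oracle for small feature spaces)
#'
#' Evaluates [fs_fitness()] for every nonempty mask over the full feature
#' set and returns the maximum. Evaluation uses one fixed fold assignment,
#' so the mask-to-fitness map is identical to the one a heuristic search
#' sees under the same `cfg`, making the oracle an upper bound for any
#' heuristic result on the same data and configuration. Ties break to the
#' lexicographically smallest mask (bit 1 most significant). Guarded to at
#' most 15 features (32767 subset evaluations).
#'
#' @param data An [fs_dataset()] with `n_features <= 15`.
#' @param cfg A [fitness_config()].
#' @return A list with `mask`, `fitness`, `accuracy`, `n_selected` and
#'   `n_evaluated`.
#' @export
exhaustive_best <- function(data, cfg = fitness_config()) {
  stopifnot(inherits(data, "fs_dataset"))
  nf <- ncol(data$X)
  if (nf > 15L)
    stop(sprintf("exhaustive search refused for %d features (limit 15)", nf),
         call. = FALSE)
  prep <- prepare_cv(data, cfg)
  best <- NULL
  best_fit <- -Inf
  n_eval <- 0L
  for (i in seq_len(2^nf - 1L)) {
    # bit 1 = most significant so enumeration order is lexicographic
    mask <- as.integer(bitwAnd(i, bitwShiftL(1L, (nf - 1L):0L)) > 0L)
    f <- fs_fitness(data, mask, cfg, folds = prep)
    n_eval <- n_eval + 1L
    if (as.numeric(f) > best_fit) {
      best_fit <- as.numeric(f)
      best <- f
    }
  }
  list(mask = attr(best, "mask"), fitness = as.numeric(best),
       accuracy = attr(best, "accuracy"),
       n_selected = attr(best, "n_selected"), n_evaluated = n_eval)
}
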