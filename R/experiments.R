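# Experiment harness: repeated BPO-S / BPO-V runs on a dataset, summary
# statistics in the best/avg/worst/std reporting convention, paired
# Wilcoxon signed-rank comparison, and convergence-curve export.

#' Configure a feature-selection experiment
#'
#' @param data An [fs_dataset()], or a [synthetic_spec()] to be generated.
#' @param variant `"s"` (BPO-S, sigmoid transfer) or `"v"` (BPO-V, |tanh|).
#' @param po A [po_config()]; its `dimensions` is overridden by the dataset
#'   gene count. Defaults to 5 parties x 6 members, 100 iterations.
#' @param fitness A [fitness_config()].
#' @param n_repeats Number of independent runs (>= 1). Each run `i` uses
#'   seed `base_seed + i - 1`.
#' @param base_seed Integer master seed.
#' @param out_dir Optional directory; when given, per-run records are
#'   appended incrementally to `runs.jsonl` as line-delimited JSON.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(data, variant = c("v", "s"),
                              po = po_config(dimensions = 1L),
                              fitness = fitness_config(),
                              n_repeats = 10L, base_seed = 1L,
                              out_dir = NULL) {
  variant <- match.arg(variant)
  if (!inherits(data, "fs_dataset") && !inherits(data, "synthetic_spec"))
    stop("'data' must be an fs_dataset or a synthetic_spec", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L)
    stop("'n_repeats' must be >= 1", call. = FALSE)
  structure(list(data = data, variant = variant, po = po, fitness = fitness,
                 n_repeats = n_repeats, base_seed = as.integer(base_seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

resolve_dataset <- function(data) {
  if (inherits(data, "synthetic_spec")) synth_expression(data)$data else data
}

#' Run a feature-selection experiment
#'
#' Executes `n_repeats` independent [po_optimize()] runs of the chosen BPO
#' variant on the dataset, with run `i` seeded `base_seed + i - 1`. Fold
#' assignment and accuracy evaluation are controlled by the fitness
#' configuration seed and therefore shared across runs, so per-run best
#' fitnesses are directly comparable and pairable across variants. The
#' accuracy reported per run is the cross-validated accuracy of the run's
#' best mask, recomputed under that fixed evaluation seed.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `bpo_runs`; each element carries `trajectory`,
#'   `best_mask`, `best_fitness`, `accuracy`, `n_selected`, `seed` and
#'   `wall_time` (seconds).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  data <- resolve_dataset(cfg$data)
  nf <- ncol(data$X)
  out_file <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out_file <- file.path(cfg$out_dir, "runs.jsonl")
    if (file.exists(out_file)) file.remove(out_file)
  }
  results <- vector("list", cfg$n_repeats)
  for (i in seq_len(cfg$n_repeats)) {
    run_seed <- cfg$base_seed + i - 1L
    po_i <- cfg$po
    po_i$dimensions <- nf
    po_i$seed <- run_seed
    fit_fn <- make_fs_fitness(data, cfg$fitness, transfer = cfg$variant)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(po_optimize(po_i, fit_fn),
                    error = function(e)
                      stop(sprintf("run %d (seed %d) failed: %s", i, run_seed,
                                   conditionMessage(e)), call. = FALSE))
    wall <- proc.time()[["elapsed"]] - t0
    acc <- knn_cv_accuracy(data, res$best_mask, cfg$fitness)
    rec <- list(trajectory = res$trajectory,
                best_mask = res$best_mask,
                best_fitness = res$best_fitness,
                accuracy = acc,
                n_selected = res$n_selected,
                seed = run_seed,
                wall_time = wall,
                variant = cfg$variant,
                n_features = nf)
    results[[i]] <- rec
    if (!is.null(out_file)) {
      line <- jsonlite::toJSON(
        c(rec[c("best_fitness", "accuracy", "n_selected", "seed",
                "wall_time", "variant", "n_features")],
          list(selected = which(res$best_mask == 1L) - 1L,  # 0-based indices
               trajectory = res$trajectory)),
        auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = out_file, append = TRUE)
    }
  }
  structure(results, class = "bpo_runs")
}

#' Summarize repeated runs
#'
#' Emits the standard reporting columns for a metaheuristic comparison:
#' best, average, worst and (sample) standard deviation of the per-run best
#' fitness, the mean number of selected genes and its percentage of the
#' full gene count, the mean recomputed accuracy, and the mean wall time.
#'
#' @param results A `bpo_runs` list from [run_experiment()], or any list of
#'   comparable records.
#' @return A one-row `data.frame`.
#' @export
summarize_runs <- function(results) {
  if (length(results) == 0L) stop("no runs to summarize", call. = FALSE)
  fit <- vapply(results, `[[`, numeric(1), "best_fitness")
  nsel <- vapply(results, `[[`, numeric(1), "n_selected")
  acc <- vapply(results, `[[`, numeric(1), "accuracy")
  wall <- vapply(results, `[[`, numeric(1), "wall_time")
  nf <- results[[1]]$n_features
  data.frame(n_runs = length(results),
             best = max(fit),
             avg = mean(fit),
             worst = min(fit),
             std = if (length(fit) > 1L) stats::sd(fit) else 0,
             mean_selected = mean(nsel),
             pct_selected = 100 * mean(nsel) / nf,
             mean_accuracy = mean(acc),
             mean_wall_time = mean(wall))
}

# Exact two-sided signed-rank p-value for the (possibly tied) differences
# `d`, by dynamic programming over the null distribution of the positive
# rank sum across all 2^k sign assignments. stats::wilcox.test declines to
# compute exact p-values in the presence of ties, which are routine when
# pairing metaheuristic best-fitness values, so this is computed here;
# tie-free results coincide with wilcox.test(exact = TRUE).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  k <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))        # doubled ranks are integers
  cnt <- numeric(sum(r2) + 1L)          # counts over 2*W+ = 0..sum(r2)
  cnt[1] <- 1
  for (ri in r2)
    cnt <- cnt + c(numeric(ri), cnt[seq_len(length(cnt) - ri)])
  probs <- cnt / 2^k
  w2 <- as.integer(round(2 * w_obs))
  p_ge <- sum(probs[(w2 + 1L):length(probs)])
  p_le <- sum(probs[seq_len(w2 + 1L)])
  min(1, 2 * min(p_ge, p_le))
}

#' Paired Wilcoxon signed-rank comparison of two run sets
#'
#' Two-sided signed-rank test on per-run best fitnesses paired by seed,
#' with the sign convention of pairwise metaheuristic comparison tables:
#' verdict `"+"` when `a` significantly exceeds `b` at level `alpha`,
#' `"-"` when significantly below, `"="` otherwise. When every pair is
#' tied the verdict is `"="` with p = 1.
#'
#' Zero differences are dropped, as in the standard signed-rank procedure.
#' For up to 50 non-zero pairs the p-value is exact, computed from the full
#' null distribution of the rank sum (ties handled through midranks); for
#' larger samples the normal approximation of [stats::wilcox.test()] is
#' used.
#'
#' @param a,b Numeric vectors of equal length (>= 5), paired by position,
#'   or `bpo_runs` lists (their best fitnesses are extracted).
#' @param alpha Significance level. Default 0.05.
#' @return A list with `p_value`, `verdict` and `statistic` (the positive
#'   rank sum W+).
#' @export
pairwise_wilcoxon <- function(a, b, alpha = 0.05) {
  if (inherits(a, "bpo_runs")) a <- vapply(a, `[[`, numeric(1), "best_fitness")
  if (inherits(b, "bpo_runs")) b <- vapply(b, `[[`, numeric(1), "best_fitness")
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 5L)
  d <- a - b
  if (all(d == 0))
    return(list(p_value = 1, verdict = "=", statistic = NA_real_))
  dn <- d[d != 0]
  r <- rank(abs(dn))
  w_plus <- sum(r[dn > 0])
  p <- if (length(dn) <= 50L) exact_signed_rank_p(d)
       else suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                alternative = "two.sided"))$p.value
  verdict <- if (p < alpha) {
    if (w_plus > sum(r) - w_plus) "+" else "-"
  } else "="
  list(p_value = p, verdict = verdict, statistic = w_plus)
}

#' Export the mean convergence curve
#'
#' Aggregates per-run global-best trajectories into a per-iteration mean,
#' minimum and maximum best-so-far curve and writes it as a tab-delimited
#' file. The mean curve inherits the non-decreasing property of each
#' trajectory. Re-exporting the same results yields a byte-identical file.
#'
#' @param results A `bpo_runs` list.
#' @param path Output file path.
#' @return The curve as a `data.frame`, invisibly.
#' @export
export_convergence <- function(results, path) {
  if (length(results) == 0L) stop("no runs to export", call. = FALSE)
  traj <- vapply(results, `[[`,
                 numeric(length(results[[1]]$trajectory)), "trajectory")
  traj <- matrix(traj, ncol = length(results))
  curve <- data.frame(iteration = seq_len(nrow(traj)),
                      mean = rowMeans(traj),
                      min = apply(traj, 1L, min),
                      max = apply(traj, 1L, max))
  utils::write.table(format(curve, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}

#' Plot convergence curves
#'
#' Convenience ggplot of the mean best-so-far fitness per iteration for one
#' or more experiments.
#'
#' @param ... Named `bpo_runs` lists (names label the curves).
#' @return A ggplot object.
#' @export
plot_convergence <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_convergence requires ggplot2", call. = FALSE)
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("run", seq_along(sets))
  dfs <- lapply(names(sets), function(nm) {
    traj <- sapply(sets[[nm]], `[[`, "trajectory")
    data.frame(iteration = seq_len(nrow(as.matrix(traj))),
               mean_best = rowMeans(as.matrix(traj)), curve = nm)
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = mean_best,
                                   colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "mean best fitness", colour = NULL) +
    ggplot2::theme_minimal()
}
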