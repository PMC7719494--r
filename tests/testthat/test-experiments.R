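test_that("summarize_runs reports best/avg/worst/std and selection columns", {
  s <- summarize_runs(fake_runs(c(1, 2, 3)))
  expect_equal(s$best, 3)
  expect_equal(s$worst, 1)
  expect_equal(s$avg, 2)
  expect_equal(s$std, 1)  # sample standard deviation

  s1 <- summarize_runs(fake_runs(2.5))
  expect_equal(s1$best, s1$worst)
  expect_equal(s1$std, 0)

  s2 <- summarize_runs(fake_runs(c(1, 1), nsel = c(40, 44), nf = 2000))
  expect_equal(s2$mean_selected, 42)
  expect_equal(s2$pct_selected, 2.1)

  expect_error(summarize_runs(list()), "no runs")
})

test_that("pairwise signed-rank test reproduces exact p-values and the verdict convention", {
  # all-tied pairs: no evidence, p = 1
  expect_equal(pairwise_wilcoxon(1:10, 1:10), list(p_value = 1, verdict = "=",
                                                   statistic = NA_real_))

  # uniform improvement: the only heavier assignment is the observed one
  set.seed(13)
  a <- rnorm(10); b <- a - 1
  res <- pairwise_wilcoxon(a, b)
  expect_equal(res$verdict, "+")
  expect_equal(res$p_value, 2 / 2^10)          # hand-derived exact tail
  expect_equal(res$p_value, signed_rank_enum_p(a - b))

  # antisymmetry of the verdict
  mirror <- pairwise_wilcoxon(b, a)
  expect_equal(mirror$verdict, "-")
  expect_equal(mirror$p_value, res$p_value)

  # exact route agrees with enumeration on random tied and untied data
  set.seed(14)
  for (i in 1:20) {
    x <- round(rnorm(9), 1)
    y <- round(rnorm(9), 1)
    if (all(x == y)) next
    expect_equal(pairwise_wilcoxon(x, y)$p_value, signed_rank_enum_p(x - y),
                 tolerance = 1e-12)
  }
  # and with wilcox.test's exact p-value when there are no ties or zeros
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(pairwise_wilcoxon(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("run_experiment produces seeded, reproducible runs with valid records", {
  spec <- synthetic_spec(30, 12, 2, effect_size = 3, seed = 5)
  cfg <- experiment_config(spec, variant = "v",
                           po = po_config(dimensions = 1, max_iterations = 8),
                           fitness = fitness_config(knn_k = 3, n_folds = 3,
                                                    seed = 2),
                           n_repeats = 3, base_seed = 100)
  runs <- run_experiment(cfg)
  expect_length(runs, 3)
  expect_equal(vapply(runs, `[[`, numeric(1), "seed"), c(100, 101, 102))
  for (r in runs) {
    expect_false(is.unsorted(r$trajectory))
    expect_equal(r$best_fitness, r$trajectory[length(r$trajectory)])
    expect_gte(r$n_selected, 1)
    expect_equal(r$n_selected, sum(r$best_mask))
    expect_lte(r$best_fitness, 1.5)
  }
  # same config, same seeds: identical fitnesses
  runs2 <- run_experiment(cfg)
  expect_identical(vapply(runs, `[[`, numeric(1), "best_fitness"),
                   vapply(runs2, `[[`, numeric(1), "best_fitness"))
})

test_that("per-run records persist as line-delimited JSON", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(30, 12, 2, effect_size = 3, seed = 5)
  cfg <- experiment_config(spec, variant = "s",
                           po = po_config(dimensions = 1, max_iterations = 5),
                           fitness = fitness_config(knn_k = 3, n_folds = 3,
                                                    seed = 2),
                           n_repeats = 2, base_seed = 7, out_dir = dir)
  runs <- run_experiment(cfg)
  lines <- readLines(file.path(dir, "runs.jsonl"))
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$best_fitness, runs[[1]]$best_fitness)
  expect_equal(rec$seed, 7)
  # masks export as 0-based selected-index lists
  expect_equal(sort(rec$selected + 1), which(runs[[1]]$best_mask == 1L))
})

test_that("convergence export is shaped, monotone and byte-stable", {
  runs <- fake_runs(c(1, 2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  curve <- export_convergence(runs, f1)
  expect_equal(nrow(curve), 2)
  expect_equal(curve$mean, c(0.75, 1.5))
  expect_false(is.unsorted(curve$mean))
  export_convergence(runs, f2)
  expect_identical(readLines(f1), readLines(f2))

  tab <- read.delim(f1)
  expect_equal(names(tab), c("iteration", "mean", "min", "max"))
})
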