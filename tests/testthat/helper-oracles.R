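# Independent oracles used across the suite. These deliberately mirror the
# published update rules in naive scalar form, separate from the package's
# vectorized implementations.

# Literal scalar transcription of the two RPPUS case tables, conditions
# tested in printed order, first match wins.
rppus_scalar <- function(x_t, x_tm1, m, use_eq1, r) {
  if (use_eq1) {
    if ((x_tm1 <= x_t && x_t <= m) || (x_tm1 >= x_t && x_t >= m))
      return(m + r * (m - x_t))
    if ((x_tm1 <= m && m <= x_t) || (x_tm1 >= m && m >= x_t))
      return(m + (2 * r - 1) * (m - x_t))
    return(m + (2 * r - 1) * (m - x_tm1))
  }
  if ((x_tm1 <= x_t && x_t <= m) || (x_tm1 >= x_t && x_t >= m))
    return(m + (2 * r - 1) * (m - x_t))
  if ((x_tm1 <= m && m <= x_t) || (x_tm1 >= m && m >= x_t))
    return(x_tm1 + r * (x_t - x_tm1))
  m + (2 * r - 1) * (m - x_tm1)
}

# Exact two-sided signed-rank p-value by explicit enumeration of all 2^k
# sign assignments (k = number of non-zero differences). Independent of the
# package's dynamic-programming route.
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  k <- length(d)
  stopifnot(k >= 1, k <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- sum(r)
  ws <- vapply(0:(2^k - 1), function(code) {
    signs <- bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(ws >= w_obs - 1e-9)
  p_le <- mean(ws <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# Plain nearest-neighbour majority vote with Euclidean distance and
# min-max scaling fit on the training rows; used to cross-check the
# packaged cross-validated accuracy on shared fold assignments.
nn_predict_oracle <- function(train, test, cl, k) {
  lo <- apply(train, 2, min); hi <- apply(train, 2, max)
  rng <- ifelse(hi - lo == 0, 1, hi - lo)
  tr <- sweep(sweep(train, 2, lo), 2, rng, "/")
  te <- sweep(sweep(test, 2, lo), 2, rng, "/")
  apply(te, 1, function(q) {
    dst <- sqrt(colSums((t(tr) - q)^2))
    nb <- cl[order(dst)[seq_len(k)]]
    as.integer(names(which.max(table(nb))))
  })
}

# Small planted two-class dataset shared by several tests.
make_planted <- function(n = 40, d = 10, informative = 2, effect = 3,
                         seed = 11) {
  synth_expression(synthetic_spec(n_samples = n, n_features = d,
                                  n_informative = informative,
                                  effect_size = effect, seed = seed))
}

small_fit_cfg <- function(seed = 99) {
  fitness_config(knn_k = 3, n_folds = 5, seed = seed)
}

# Hand-built run records for summary-statistics tests.
fake_runs <- function(fits, nsel = rep(5, length(fits)), nf = 10) {
  structure(lapply(seq_along(fits), function(i)
    list(best_fitness = fits[i], n_selected = nsel[i], accuracy = 0.9,
         wall_time = 0.1, n_features = nf,
         trajectory = c(fits[i] / 2, fits[i]))),
    class = "bpo_runs")
}
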