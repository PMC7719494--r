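# A cheap deterministic continuous objective for engine-level tests.
sphere_fit <- function(x) -sum((x - 0.25)^2)

test_that("rppus_update reproduces hand-evaluated cases", {
  # improved-fitness table, first case: x ascending toward the reference
  expect_equal(rppus_update(x_t = 3, x_tm1 = 1, m_star = 5,
                            use_eq1 = TRUE, r = 0.5), 6)
  # worsened-fitness table, middle case: reference between past and present
  expect_equal(rppus_update(x_t = 3, x_tm1 = 1, m_star = 2,
                            use_eq1 = FALSE, r = 0.5), 2)
  # full degeneracy collapses every branch onto the reference
  for (eq1 in c(TRUE, FALSE))
    for (r in c(0, 0.3, 1))
      expect_equal(rppus_update(7, 7, 7, eq1, r = r), 7)
})

test_that("vectorized rppus_update equals the scalar oracle on random tuples", {
  set.seed(17)
  n <- 1500
  x_t <- runif(n, -6, 6); x_tm1 <- runif(n, -6, 6)
  m <- runif(n, -6, 6); r <- runif(n)
  # include boundary-equality tuples explicitly
  x_tm1[1:50] <- x_t[1:50]
  m[26:75] <- x_t[26:75]
  for (eq1 in c(TRUE, FALSE)) {
    got <- rppus_update(x_t, x_tm1, m, eq1, r = r)
    want <- mapply(rppus_scalar, x_t, x_tm1, m, MoreArgs = list(use_eq1 = eq1),
                   r = r)
    expect_identical(got, unname(want))
  }
})

test_that("initialization builds the party/constituency geometry", {
  set.seed(2)
  cfg <- po_config(parties = 5, members_per_party = 6, dimensions = 10,
                   max_iterations = 10)
  pop <- init_population(cfg, sphere_fit)
  expect_equal(nrow(pop$pos), 30)
  expect_length(pop$leaders, 5)
  expect_length(pop$winners, 6)
  expect_equal(as.vector(table(pop$party)), rep(6L, 5))
  expect_equal(as.vector(table(pop$constituency)), rep(5L, 6))
  expect_true(all(pop$pos >= -1 & pop$pos <= 1))
  expect_identical(pop$prev_pos, pop$pos)
  expect_identical(pop$prev_fit, pop$fit)
  # leaders attain the party maxima, winners the constituency maxima
  for (i in 1:5)
    expect_equal(pop$fit[pop$leaders[i]], max(pop$fit[pop$party == i]))
  for (j in 1:6)
    expect_equal(pop$fit[pop$winners[j]], max(pop$fit[pop$constituency == j]))

  # constant fitness: every tie breaks to the lowest index
  set.seed(3)
  cfg2 <- po_config(parties = 2, members_per_party = 2, dimensions = 1,
                    max_iterations = 1)
  pop2 <- init_population(cfg2, function(x) 1)
  expect_equal(pop2$leaders, c(1L, 3L))   # first member of each party
  expect_equal(pop2$winners, c(1L, 2L))   # party 1's candidate per constituency

  # determinism under seeding
  set.seed(42); a <- init_population(cfg, sphere_fit)
  set.seed(42); b <- init_population(cfg, sphere_fit)
  expect_identical(a$pos, b$pos)

  expect_error(po_config(parties = 1, members_per_party = 3, dimensions = 2),
               "parties")
  expect_error(po_config(parties = 2, members_per_party = 2, dimensions = 0),
               "dimensions")
})

test_that("run_election picks argmax per constituency and party", {
  set.seed(4)
  cfg <- po_config(parties = 2, members_per_party = 2, dimensions = 1,
                   max_iterations = 1)
  pop <- init_population(cfg, function(x) 0)
  # rows: party1 = (m1, m2), party2 = (m1, m2); constituency j = j-th members
  pop$fit <- c(3, 1, 2, 4)
  pop <- run_election(pop)
  expect_equal(pop$leaders, c(1L, 4L))   # fitness 3 and 4
  expect_equal(pop$winners, c(1L, 4L))   # constituency 1 -> 3, 2 -> 4
  expect_equal(pop$best$fitness, 4)
  # archive is monotone: worsening all fitnesses must not lower the best
  pop$fit <- rep(-1, 4)
  pop <- run_election(pop)
  expect_equal(pop$best$fitness, 4)
})

test_that("election campaign snapshots the recent past and respects degeneracy", {
  set.seed(9)
  cfg <- po_config(parties = 2, members_per_party = 2, dimensions = 3,
                   max_iterations = 1)
  pop <- init_population(cfg, sphere_fit)
  old_pos <- pop$pos
  old_fit <- pop$fit
  pop2 <- election_campaign(pop)
  expect_identical(pop2$prev_pos, old_pos)
  expect_identical(pop2$prev_fit, old_fit)
  expect_true(all(pop2$pos >= -6 & pop2$pos <= 6))

  # a member that is its own leader and winner, with x_t = x_tm1 = m_star,
  # stays exactly in place
  pop$pos[] <- 0.5
  pop$prev_pos[] <- 0.5
  pop$fit <- c(4, 1, 2, 3)   # row 1 leads party 1 and wins constituency 1
  pop <- run_election(pop)
  moved <- election_campaign(pop)
  expect_equal(moved$pos[1, ], rep(0.5, 3))
})

test_that("party switching conserves the population multiset", {
  set.seed(21)
  cfg <- po_config(parties = 3, members_per_party = 4, dimensions = 2,
                   max_iterations = 1)
  pop <- init_population(cfg, sphere_fit)

  expect_identical(party_switching(pop, 0)$pos, pop$pos)

  for (rep_i in 1:100) {
    lam <- runif(1)
    out <- party_switching(pop, lam)
    expect_equal(sort(out$fit), sort(pop$fit))
    expect_equal(out$pos[order(out$fit), ], pop$pos[order(pop$fit), ])
    expect_equal(as.vector(table(out$party)), rep(4L, 3))
    expect_equal(as.vector(table(out$constituency)), rep(3L, 4))
  }
})

test_that("parliamentary affairs never worsens a winner", {
  set.seed(33)
  cfg <- po_config(parties = 3, members_per_party = 4, dimensions = 3,
                   max_iterations = 1)
  for (rep_i in 1:100) {
    pop <- init_population(cfg, sphere_fit)
    before <- sum(pop$fit[pop$winners])
    out <- parliamentary_affairs(pop, sphere_fit)
    after <- sum(out$fit[out$winners])
    expect_gte(after, before - 1e-12)
  }
})

test_that("po_optimize is deterministic, bounded, and monotone", {
  cfg <- po_config(parties = 3, members_per_party = 3, dimensions = 4,
                   max_iterations = 1, seed = 8)
  r1 <- po_optimize(cfg, sphere_fit)
  expect_length(r1$trajectory, 1)

  cfg$max_iterations <- 25L
  a <- po_optimize(cfg, sphere_fit)
  b <- po_optimize(cfg, sphere_fit)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$best_position, b$best_position)
  expect_false(is.unsorted(a$trajectory))

  expect_error(po_optimize(cfg, function(x) NaN), "non-finite")
})

test_that("the optimizer solves a separable one-max objective", {
  # count of set bits after S-shaped binarization, known optimum 1.0
  onemax <- function(x) {
    bits <- binarize_position(x, "s")
    structure(mean(bits), mask = bits)
  }
  hits <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    cfg <- po_config(parties = 5, members_per_party = 6, dimensions = 8,
                     max_iterations = 100, seed = 1000 + s)
    res <- po_optimize(cfg, onemax)
    if (res$best_fitness >= 1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
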