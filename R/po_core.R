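# Continuous Political Optimizer engine: population structure and the four
# iterated phases (election campaign, party switching, election,
# parliamentary affairs). Generic over any fitness callable defined on
# continuous positions; the engine MAXIMIZES.
#
# Population layout: p parties x m members stored row-wise in a
# (p*m) x d matrix. Row i belongs to party (i-1) %/% m + 1 and contests
# constituency (i-1) %% m + 1, so each constituency holds the j-th member
# of every party. Party switching swaps member records between row slots;
# the slot keeps its party/constituency meaning.

#' Configuration for the Political Optimizer
#'
#' @param parties Number of political parties `p` (>= 2). Default 5.
#' @param members_per_party Members per party `m` (>= 2); also the number of
#'   constituencies. Default 6, giving the default 30 search agents.
#' @param dimensions Dimensionality `d` of a position vector (number of
#'   features for the selection problem).
#' @param max_iterations Number of optimization iterations `T_max`.
#'   Default 100.
#' @param lambda_max Upper limit of the party-switching rate, in \[0, 1\].
#'   The per-iteration rate decays linearly from this value to 0. Default 1.
#' @param init_range Length-2 numeric, the uniform initialization interval
#'   for positions. Default `c(-1, 1)`.
#' @param clip_range Length-2 numeric, hard bounds applied to every updated
#'   coordinate. Default `c(-6, 6)`, keeping transfer functions out of total
#'   saturation.
#' @param seed Integer seed for the run's random stream.
#' @return An object of class `po_config`.
#' @export
po_config <- function(parties = 5L, members_per_party = 6L, dimensions,
                      max_iterations = 100L, lambda_max = 1,
                      init_range = c(-1, 1), clip_range = c(-6, 6),
                      seed = 1L) {
  parties <- as.integer(parties)
  members_per_party <- as.integer(members_per_party)
  dimensions <- as.integer(dimensions)
  max_iterations <- as.integer(max_iterations)
  if (is.na(parties) || parties < 2L)
    stop("'parties' must be an integer >= 2", call. = FALSE)
  if (is.na(members_per_party) || members_per_party < 2L)
    stop("'members_per_party' must be an integer >= 2", call. = FALSE)
  if (is.na(dimensions) || dimensions < 1L)
    stop("'dimensions' must be an integer >= 1", call. = FALSE)
  if (is.na(max_iterations) || max_iterations < 1L)
    stop("'max_iterations' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(lambda_max) || lambda_max < 0 || lambda_max > 1)
    stop("'lambda_max' must lie in [0, 1]", call. = FALSE)
  stopifnot(length(init_range) == 2L, init_range[1] < init_range[2],
            length(clip_range) == 2L, clip_range[1] < clip_range[2])
  structure(list(parties = parties, members_per_party = members_per_party,
                 dimensions = dimensions, max_iterations = max_iterations,
                 lambda_max = lambda_max, init_range = init_range,
                 clip_range = clip_range, seed = as.integer(seed)),
            class = "po_config")
}

#' @export
print.po_config <- function(x, ...) {
  cat("Political Optimizer configuration\n")
  cat(sprintf("  %d parties x %d members = %d agents, d = %d\n",
              x$parties, x$members_per_party,
              x$parties * x$members_per_party, x$dimensions))
  cat(sprintf("  T_max = %d, lambda_max = %g, init [%g, %g], clip [%g, %g]\n",
              x$max_iterations, x$lambda_max, x$init_range[1],
              x$init_range[2], x$clip_range[1], x$clip_range[2]))
  invisible(x)
}

clip_positions <- function(x, range) {
  pmin(pmax(x, range[1]), range[2])
}

# Evaluate fitness_fn on the rows listed in `rows`; stores the fitness and
# any cached binary mask the callable attaches as attr(value, "mask").
evaluate_members <- function(pop, fitness_fn, rows = seq_len(nrow(pop$pos))) {
  for (i in rows) {
    f <- fitness_fn(pop$pos[i, ])
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
      stop(sprintf("fitness is non-finite for member %d (party %d, constituency %d)",
                   i, pop$party[i], pop$constituency[i]), call. = FALSE)
    pop$fit[i] <- as.numeric(f)
    msk <- attr(f, "mask")
    if (!is.null(msk)) pop$mask[i, ] <- msk
  }
  pop
}

#' Initialize a Political Optimizer population
#'
#' Draws `p * m` member positions uniformly from the initialization range,
#' evaluates them, sets the recent-past state equal to the initial state
#' (so the equal-fitness update rule applies on the first campaign), and
#' computes party leaders, constituency winners and the global best.
#'
#' @param config A [po_config()].
#' @param fitness_fn Callable taking one continuous position vector and
#'   returning one finite numeric fitness (larger is better). May attach a
#'   binary mask as `attr(value, "mask")`.
#' @return A population object of class `po_population`.
#' @export
init_population <- function(config, fitness_fn) {
  stopifnot(inherits(config, "po_config"))
  p <- config$parties; m <- config$members_per_party; d <- config$dimensions
  np <- p * m
  pos <- matrix(stats::runif(np * d, config$init_range[1], config$init_range[2]),
                nrow = np, ncol = d)
  pop <- list(
    pos = pos, prev_pos = pos,
    fit = rep(NA_real_, np), prev_fit = rep(NA_real_, np),
    mask = matrix(NA_integer_, np, d),
    party = rep(seq_len(p), each = m),
    constituency = rep(seq_len(m), times = p),
    leaders = integer(p), winners = integer(m),
    best = list(fitness = -Inf, position = NULL, mask = NULL),
    iteration = 0L, config = config)
  class(pop) <- "po_population"
  pop <- evaluate_members(pop, fitness_fn)
  pop$prev_fit <- pop$fit
  run_election(pop)
}

#' Recent past-based position update (RPPUS)
#'
#' Coordinate update used during the election campaign. Each coordinate
#' moves relative to a reference coordinate `m_star` (the party leader's or
#' constituency winner's value), using the previous-iteration coordinate to
#' decide which of three piecewise cases applies. Two case tables exist:
#' the first is used when the member's fitness improved (or held) since the
#' previous iteration, the second when it worsened. Cases are tested in
#' order and the first match wins, so equality boundaries fall into the
#' earliest matching case; the three conditions cover every ordering of the
#' inputs.
#'
#' All arguments are vectorized coordinate-wise.
#'
#' @param x_t Current coordinate(s).
#' @param x_tm1 Previous-iteration coordinate(s).
#' @param m_star Reference coordinate(s) (leader or winner).
#' @param use_eq1 Logical; `TRUE` selects the improved-fitness case table.
#' @param r Uniform(0,1) draw(s); defaults to fresh draws from the current
#'   random stream, one per coordinate.
#' @return Updated coordinate(s), unclipped (the caller applies bounds).
#' @examples
#' rppus_update(x_t = 3, x_tm1 = 1, m_star = 5, use_eq1 = TRUE, r = 0.5)
#' @export
rppus_update <- function(x_t, x_tm1, m_star, use_eq1,
                         r = stats::runif(length(x_t))) {
  n <- length(x_t)
  stopifnot(length(x_tm1) == n)
  m <- rep_len(m_star, n)
  r <- rep_len(r, n)
  e1 <- rep_len(as.logical(use_eq1), n)

  c1 <- (x_tm1 <= x_t & x_t <= m) | (x_tm1 >= x_t & x_t >= m)
  c2 <- !c1 & ((x_tm1 <= m & m <= x_t) | (x_tm1 >= m & m >= x_t))
  c3 <- !c1 & !c2

  out <- numeric(n)
  i <- e1 & c1;  out[i] <- m[i] + r[i] * (m[i] - x_t[i])
  i <- e1 & c2;  out[i] <- m[i] + (2 * r[i] - 1) * (m[i] - x_t[i])
  i <- e1 & c3;  out[i] <- m[i] + (2 * r[i] - 1) * (m[i] - x_tm1[i])
  i <- !e1 & c1; out[i] <- m[i] + (2 * r[i] - 1) * (m[i] - x_t[i])
  i <- !e1 & c2; out[i] <- x_tm1[i] + r[i] * (x_t[i] - x_tm1[i])
  i <- !e1 & c3; out[i] <- m[i] + (2 * r[i] - 1) * (m[i] - x_tm1[i])
  out
}

#' Election campaign phase
#'
#' Every member updates its position twice through [rppus_update()]: first
#' relative to its party leader's position, then relative to its
#' constituency winner's position, with a fresh uniform draw per coordinate
#' per update. The improved-fitness case table is chosen when the member's
#' current fitness is at least its previous fitness. Before updating, the
#' current position and fitness are snapshotted into the recent-past state.
#' Leader and winner positions are frozen at phase entry.
#'
#' @param pop A `po_population`.
#' @return The updated population (fitnesses are stale until re-evaluated).
#' @export
election_campaign <- function(pop) {
  stopifnot(inherits(pop, "po_population"))
  cfg <- pop$config
  np <- nrow(pop$pos); d <- ncol(pop$pos)

  leader_pos <- pop$pos[pop$leaders[pop$party], , drop = FALSE]
  winner_pos <- pop$pos[pop$winners[pop$constituency], , drop = FALSE]
  use_eq1 <- pop$fit >= pop$prev_fit

  pop$prev_pos <- pop$pos
  pop$prev_fit <- pop$fit
  prev <- as.vector(pop$prev_pos)
  e1 <- rep(use_eq1, times = d)  # column-major expansion, one flag per member

  x1 <- rppus_update(as.vector(pop$pos), prev, as.vector(leader_pos), e1,
                     r = stats::runif(np * d))
  x1 <- clip_positions(x1, cfg$clip_range)
  x2 <- rppus_update(x1, prev, as.vector(winner_pos), e1,
                     r = stats::runif(np * d))
  pop$pos <- matrix(clip_positions(x2, cfg$clip_range), np, d)
  pop
}

#' Party switching phase
#'
#' Each member is independently selected with probability `lambda_t`; a
#' selected member is exchanged with the least-fit member of a uniformly
#' chosen different party (the two trade party and constituency
#' assignments). Member count and per-party sizes are invariant.
#'
#' @param pop A `po_population`.
#' @param lambda_t Switching probability for this iteration, in \[0, 1\].
#' @return The updated population.
#' @export
party_switching <- function(pop, lambda_t) {
  stopifnot(inherits(pop, "po_population"),
            is.numeric(lambda_t), lambda_t >= 0, lambda_t <= 1)
  p <- pop$config$parties
  if (p < 2L || lambda_t == 0) return(pop)
  np <- nrow(pop$pos)
  selected <- which(stats::runif(np) < lambda_t)
  for (i in selected) {
    others <- which(seq_len(p) != pop$party[i])
    target <- others[sample.int(length(others), 1L)]
    rows_t <- which(pop$party == target)
    j <- rows_t[which.min(pop$fit[rows_t])]  # least fit; lowest index on ties
    swap <- c(i, j); rev_swap <- c(j, i)
    pop$pos[swap, ] <- pop$pos[rev_swap, ]
    pop$prev_pos[swap, ] <- pop$prev_pos[rev_swap, ]
    pop$mask[swap, ] <- pop$mask[rev_swap, ]
    pop$fit[swap] <- pop$fit[rev_swap]
    pop$prev_fit[swap] <- pop$prev_fit[rev_swap]
  }
  pop
}

#' Election phase
#'
#' Recomputes, from current fitnesses, the winner of each constituency
#' (best among the p contesting candidates), the leader of each party (best
#' among its m members), and updates the global-best archive. All ties
#' break to the lowest index, so results are deterministic.
#'
#' @param pop A `po_population` with fitnesses evaluated at the current
#'   positions.
#' @return The updated population.
#' @export
run_election <- function(pop) {
  stopifnot(inherits(pop, "po_population"))
  p <- pop$config$parties; m <- pop$config$members_per_party
  for (i in seq_len(p)) {
    rows <- which(pop$party == i)
    pop$leaders[i] <- rows[which.max(pop$fit[rows])]
  }
  for (j in seq_len(m)) {
    rows <- which(pop$constituency == j)  # ascending party order
    pop$winners[j] <- rows[which.max(pop$fit[rows])]
  }
  b <- which.max(pop$fit)
  if (pop$fit[b] > pop$best$fitness) {
    pop$best <- list(fitness = pop$fit[b], position = pop$pos[b, ],
                     mask = pop$mask[b, ])
  }
  pop
}

#' Parliamentary affairs phase
#'
#' Each constituency winner (parliamentarian) forms a trial position
#' relative to a distinct, uniformly chosen fellow winner `w`:
#' `trial_k = w_k + (2r - 1) * |w_k - winner_k|` with a fresh uniform draw
#' per coordinate. The trial replaces the winner's member record only when
#' its fitness is strictly better, so no winner's fitness can decrease
#' here. With a single constituency the phase is a no-op.
#'
#' @param pop A `po_population` with current winners.
#' @param fitness_fn The fitness callable (see [init_population()]).
#' @return The updated population.
#' @export
parliamentary_affairs <- function(pop, fitness_fn) {
  stopifnot(inherits(pop, "po_population"))
  m <- pop$config$members_per_party
  if (m < 2L) return(pop)
  d <- ncol(pop$pos)
  for (j in seq_len(m)) {
    wj <- pop$winners[j]
    others <- setdiff(seq_len(m), j)
    wr <- pop$winners[others[sample.int(length(others), 1L)]]
    r <- stats::runif(d)
    trial <- pop$pos[wr, ] + (2 * r - 1) * abs(pop$pos[wr, ] - pop$pos[wj, ])
    trial <- clip_positions(trial, pop$config$clip_range)
    f <- fitness_fn(trial)
    if (is.finite(f) && f > pop$fit[wj]) {
      pop$pos[wj, ] <- trial
      pop$fit[wj] <- as.numeric(f)
      msk <- attr(f, "mask")
      if (!is.null(msk)) pop$mask[wj, ] <- msk
      if (pop$fit[wj] > pop$best$fitness)
        pop$best <- list(fitness = pop$fit[wj], position = pop$pos[wj, ],
                         mask = pop$mask[wj, ])
    }
  }
  pop
}

#' Run the Political Optimizer
#'
#' Seeds the random stream from the configuration, initializes the
#' population once, then iterates election campaign, party switching,
#' fitness evaluation, election and parliamentary affairs for
#' `max_iterations` rounds. The party-switching rate anneals linearly,
#' `lambda_t = lambda_max * (1 - t / T_max)`, trading exploration for
#' exploitation. The returned trajectory records the global-best fitness at
#' the end of each iteration and is non-decreasing.
#'
#' @param config A [po_config()].
#' @param fitness_fn Fitness callable (see [init_population()]); the engine
#'   maximizes it. Pass a negated objective to minimize.
#' @return A list of class `bpo_run` with elements `trajectory`
#'   (length `max_iterations`), `best_fitness`, `best_position`,
#'   `best_mask` (NULL unless the callable caches masks), `n_selected`,
#'   `seed`, and `config`.
#' @examples
#' cfg <- po_config(parties = 2, members_per_party = 3, dimensions = 2,
#'                  max_iterations = 5, seed = 7)
#' res <- po_optimize(cfg, function(x) -sum(x^2))
#' res$trajectory
#' @export
po_optimize <- function(config, fitness_fn) {
  stopifnot(inherits(config, "po_config"), is.function(fitness_fn))
  set.seed(config$seed)
  pop <- init_population(config, fitness_fn)
  tmax <- config$max_iterations
  traj <- numeric(tmax)
  for (t in seq_len(tmax)) {
    lambda_t <- config$lambda_max * (1 - t / tmax)
    pop <- election_campaign(pop)
    pop <- party_switching(pop, lambda_t)
    pop <- evaluate_members(pop, fitness_fn)
    pop <- run_election(pop)
    pop <- parliamentary_affairs(pop, fitness_fn)
    pop$iteration <- t
    traj[t] <- pop$best$fitness
  }
  best_mask <- pop$best$mask
  if (!is.null(best_mask) && anyNA(best_mask)) best_mask <- NULL
  structure(list(trajectory = traj,
                 best_fitness = pop$best$fitness,
                 best_position = pop$best$position,
                 best_mask = best_mask,
                 n_selected = if (is.null(best_mask)) NA_integer_
                              else sum(best_mask),
                 seed = config$seed,
                 config = config),
            class = "bpo_run")
}

#' @export
print.bpo_run <- function(x, ...) {
  cat("Political Optimizer run\n")
  cat(sprintf("  best fitness %.6g after %d iterations (seed %d)\n",
              x$best_fitness, length(x$trajectory), x$seed))
  if (!is.null(x$best_mask))
    cat(sprintf("  selected features: %d / %d\n", x$n_selected,
                length(x$best_mask)))
  invisible(x)
}
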