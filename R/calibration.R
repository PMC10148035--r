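#' Experimental (or pseudo-experimental) protein time series
#'
#' @param protein one of `"PodJL"`, `"PodJS"`, `"CtrA"` (total CtrA) or
#'   any aggregate accepted by [species_total()].
#' @param times sampling times (min from cycle birth).
#' @param values normalized observed levels (max 1). May also be a list
#'   of two vectors named `cycle2`, `cycle3` (per-cycle pseudo-data from
#'   the fixture generator).
#' @param weight objective weight of this series.
#' @return object of class `caulo_series`.
#' @export
experimental_series <- function(protein, times, values, weight) {
  n <- if (is.list(values)) length(values[[1]]) else length(values)
  stopifnot(length(times) == n)
  structure(list(protein = protein, times = times, values = values,
                 n = n, weight = weight), class = "caulo_series")
}

#' Normalize a measured series by its maximum
#'
#' @param raw numeric vector with `max(raw) > 0`.
#' @return `raw / max(raw)`; the maximum of the output is 1. Idempotent.
#' @export
normalize_series <- function(raw) {
  m <- max(raw)
  if (!is.finite(m) || m <= 0) stop("series maximum must be positive")
  raw / m
}

#' Least-squares scale factor between simulation and data
#'
#' The factor minimizing `sum((x - scale * y)^2)`, i.e.
#' `sum(x * y) / sum(y^2)`: normalized data are scaled onto the
#' simulated series before computing the fit cost.
#'
#' @param sim simulated values `x`.
#' @param data normalized data values `y` with `sum(y^2) > 0`.
#' @return the scale factor.
#' @export
fit_scale <- function(sim, data) {
  ss <- sum(data^2)
  if (ss <= 0) stop("degenerate data series (sum of squares is zero)")
  sum(sim * data) / ss
}

## Values of a series for a given cycle label ("cycle2"/"cycle3").
.series_values <- function(series, cycle) {
  if (is.list(series$values)) series$values[[cycle]] else series$values
}

## Simulated whole-cell totals of a series' protein at its time points.
.sim_at_times <- function(traj, protein, times) {
  tot <- species_total(traj, protein)
  stats::approx(traj$times, tot, xout = pmin(times, max(traj$times)),
                rule = 2)$y
}

#' Temporal-fit objective
#'
#' Sum over simulated cycles 2 and 3 and over the observed proteins of
#' `(weight / n) * sum(((x_i - y_i) / max(y))^2)`, where `x` is the
#' simulated whole-cell total at the data time points and `y` the
#' normalized data scaled onto the simulation by [fit_scale()], plus a
#' replication-timing penalty `max(0, |T_ini - 25| - 5)^2` (applied once
#' per evaluation; initiation within 20-30 min is not penalized).
#'
#' @param trajs named list with trajectories `cycle2` and `cycle3`.
#' @param data list of [experimental_series()].
#' @param T_ini replication initiation time of the reporting cycle (min).
#' @return nonnegative cost.
#' @export
objective_f1 <- function(trajs, data, T_ini) {
  cost <- 0
  for (cyc in c("cycle2", "cycle3")) {
    traj <- trajs[[cyc]]
    if (is.null(traj)) stop("missing trajectory for ", cyc)
    for (s in data) {
      x <- .sim_at_times(traj, s$protein, s$times)
      y0 <- .series_values(s, cyc)
      y <- fit_scale(x, y0) * y0
      m <- max(y)
      if (m <= 0) m <- 1
      cost <- cost + (s$weight / s$n) * sum(((x - y) / m)^2)
    }
  }
  cost + max(0, abs(T_ini - 25) - 5)^2
}

## Cycle-averaged regional means of a protein total: new pole (compartment
## 1), old pole (compartment N), central mean (2..N-1), all-compartment
## mean. Time averages are trapezoidal over the trajectory.
.region_means <- function(traj, what) {
  members <- if (what %in% names(.totals_map)) .totals_map[[what]] else what
  prof <- apply(traj$conc[members, , , drop = FALSE], c(2, 3), sum)
  tt <- traj$times
  w <- diff(tt)
  tavg <- as.vector((prof[, -ncol(prof), drop = FALSE] %*% w +
                     prof[, -1, drop = FALSE] %*% w) / (2 * sum(w)))
  N <- traj$N
  c(new = tavg[1], old = tavg[N], central = mean(tavg[2:(N - 1)]),
    all = mean(tavg))
}

#' Spatial penalty of the PopZ pattern
#'
#' Penalizes deviation from the required bipolar wild-type pattern:
#' zero when the cycle-averaged new-pole PopZ reaches 4x the central
#' mean and the old-pole PopZ 1.5x the central mean; shortfalls are
#' squared after normalization by the all-compartment mean. Surpluses
#' are not penalized.
#'
#' @param traj a `caulo_trajectory` of one cycle.
#' @return nonnegative penalty.
#' @export
spatial_penalty_popz <- function(traj) {
  r <- .region_means(traj, "PopZ")
  if (r[["all"]] <= 0) stop("all-compartment PopZ average is zero")
  (min(0, (r[["new"]] - 4 * r[["central"]]) / r[["all"]]))^2 +
    (min(0, (r[["old"]] - 1.5 * r[["central"]]) / r[["all"]]))^2
}

#' Spatial penalty of the DivK~P pattern
#'
#' Favors transient new-pole accumulation of total DivK~P: penalizes a
#' cycle-averaged new-pole level short of 2x the central mean.
#'
#' @inheritParams spatial_penalty_popz
#' @return nonnegative penalty.
#' @export
spatial_penalty_divk <- function(traj) {
  r <- .region_means(traj, "DivKp")
  if (r[["all"]] <= 0) stop("all-compartment DivK~P average is zero")
  (min(0, (r[["new"]] - 2 * r[["central"]]) / r[["all"]]))^2
}

#' Spatial-penalty objective
#'
#' Sum over cycles 2 and 3 of `100 * SP_PopZ + 1 * SP_DivK`.
#'
#' @param trajs named list with trajectories `cycle2` and `cycle3`.
#' @param weights penalty weights (PopZ 100, DivK 1).
#' @return nonnegative cost.
#' @export
objective_f2 <- function(trajs, weights = c(PopZ = 100, DivK = 1)) {
  cost <- 0
  for (cyc in c("cycle2", "cycle3")) {
    traj <- trajs[[cyc]]
    if (is.null(traj)) stop("missing trajectory for ", cyc)
    cost <- cost + weights[["PopZ"]] * spatial_penalty_popz(traj) +
      weights[["DivK"]] * spatial_penalty_divk(traj)
  }
  unname(cost)
}

#' Evaluate both objectives for a parameter table
#'
#' Simulates three consecutive wild-type cycles and scores cycles 2 and
#' 3 with [objective_f1()] and [objective_f2()]. A run that fails to
#' initiate replication (no cycles to score) is assigned a large
#' penalty cost on both objectives.
#'
#' @param p parameter table.
#' @param data list of [experimental_series()].
#' @param N compartment count (a smaller grid speeds up the search).
#' @param dt_sample sampling interval (min).
#' @return numeric `c(f1, f2)`.
#' @export
evaluate_objectives <- function(p, data, N = 4, dt_sample = 2) {
  cycles <- tryCatch(
    run_strain("WT", p, n_cycles = 3, N = N, dt_sample = dt_sample),
    error = function(e) NULL)
  if (is.null(cycles) || length(cycles) < 3)
    return(c(f1 = 1e6, f2 = 1e6))
  trajs <- list(cycle2 = cycles[[2]], cycle3 = cycles[[3]])
  f1 <- objective_f1(trajs, data, T_ini = cycles[[3]]$events$T_ini)
  f2 <- objective_f2(trajs)
  c(f1 = f1, f2 = f2)
}

## ---- NSGA-II machinery -------------------------------------------------

## Pareto dominance: TRUE if a dominates b (minimization).
.dominates <- function(a, b) all(a <= b) && any(a < b)

## Fast nondominated sort; returns integer front index per row of F.
.nds_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dominated_by <- vector("list", n)
  ndom <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && .dominates(F[i, ], F[j, ]))
      dominated_by[[i]] <- c(dominated_by[[i]], j)
    if (i != j && .dominates(F[j, ], F[i, ])) ndom[i] <- ndom[i] + 1L
  }
  front <- which(ndom == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) for (j in dominated_by[[i]]) {
      ndom[j] <- ndom[j] - 1L
      if (ndom[j] == 0L) nxt <- c(nxt, j)
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  rank
}

## Crowding distance within one front.
.crowding <- function(F) {
  n <- nrow(F)
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

## Simulated binary crossover + polynomial mutation, clipped to bounds.
.sbx_mutate <- function(p1, p2, lb, ub, eta_c = 15, eta_m = 20, pm = NULL) {
  d <- length(p1)
  if (is.null(pm)) pm <- 1 / d
  u <- stats::runif(d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
  child <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  mut <- stats::runif(d) < pm
  if (any(mut)) {
    u2 <- stats::runif(sum(mut))
    delta <- ifelse(u2 < 0.5, (2 * u2)^(1 / (eta_m + 1)) - 1,
                    1 - (2 * (1 - u2))^(1 / (eta_m + 1)))
    child[mut] <- child[mut] + delta * (ub[mut] - lb[mut])
  }
  pmin(pmax(child, lb), ub)
}

#' Estimate the free parameters by two-objective evolutionary search
#'
#' Nondominated-sorting genetic algorithm (NSGA-II style: fast
#' nondominated sort, crowding-distance diversity, simulated binary
#' crossover, polynomial mutation, elitist selection) minimizing
#' `(f1, f2)` over the estimated parameter group. Bounds are 0.4x and
#' 1.5x of the seed values; the seed vector itself is injected into the
#' initial population, so each calibration round can resume from the
#' previous round's verified winner. Fully reproducible under a fixed
#' RNG seed.
#'
#' @param seed_params parameter table whose estimated group seeds the
#'   search and defines the bounds.
#' @param data list of [experimental_series()] for [objective_f1()].
#' @param generations,population GA budget.
#' @param rng_seed integer RNG seed.
#' @param N compartment count used during evaluation (the coarse-grid
#'   pre-fit pass; refit on 10 compartments by reseeding).
#' @param evaluator objective function `(param table, data) -> c(f1, f2)`;
#'   defaults to [evaluate_objectives()].
#' @return list with `pareto` (data frame of estimated-parameter columns
#'   plus `f1`, `f2`; mutually nondominated), `bounds`, and the
#'   evaluation `history` of best f1 per generation.
#' @export
estimate_parameters <- function(seed_params, data, generations = 5,
                                population = 12, rng_seed = 1, N = 4,
                                evaluator = NULL) {
  est <- seed_params$group == "estimated"
  if (!any(est)) stop("no estimated parameters in the seed set")
  nm <- seed_params$name[est]
  seed <- seed_params$value[est]
  lb <- 0.4 * seed
  ub <- 1.5 * seed
  if (is.null(evaluator))
    evaluator <- function(pt, dat) evaluate_objectives(pt, dat, N = N)
  as_table <- function(x) {
    v <- x; names(v) <- nm
    set_params(seed_params, v)
  }
  set.seed(rng_seed)
  d <- length(seed)
  pop <- matrix(stats::runif(population * d, rep(lb, each = population),
                             rep(ub, each = population)),
                nrow = population)
  pop[1, ] <- seed  # resumable seeding
  scores <- t(apply(pop, 1, function(x) evaluator(as_table(x), data)))
  history <- numeric(generations)
  for (gen in seq_len(generations)) {
    rank <- .nds_rank(scores)
    crowd <- numeric(population)
    for (r in unique(rank)) {
      i <- which(rank == r)
      crowd[i] <- .crowding(scores[i, , drop = FALSE])
    }
    tournament <- function() {
      ij <- sample.int(population, 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j] || (rank[i] == rank[j] && crowd[i] > crowd[j])) i else j
    }
    kids <- t(vapply(seq_len(population), function(k)
      .sbx_mutate(pop[tournament(), ], pop[tournament(), ], lb, ub),
      numeric(d)))
    kscores <- t(apply(kids, 1, function(x) evaluator(as_table(x), data)))
    allpop <- rbind(pop, kids)
    allsc <- rbind(scores, kscores)
    arank <- .nds_rank(allsc)
    acrowd <- numeric(nrow(allsc))
    for (r in unique(arank)) {
      i <- which(arank == r)
      acrowd[i] <- .crowding(allsc[i, , drop = FALSE])
    }
    keep <- order(arank, -acrowd)[seq_len(population)]
    pop <- allpop[keep, , drop = FALSE]
    scores <- allsc[keep, , drop = FALSE]
    history[gen] <- min(scores[, 1])
  }
  rank <- .nds_rank(scores)
  front <- which(rank == 1L)
  pareto <- as.data.frame(pop[front, , drop = FALSE])
  names(pareto) <- nm
  pareto$f1 <- scores[front, 1]
  pareto$f2 <- scores[front, 2]
  ## drop duplicated points so the front is a set
  pareto <- unique(pareto)
  list(pareto = pareto,
       bounds = data.frame(name = nm, lower = lb, upper = ub),
       history = history)
}
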