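#' No-flux diffusion operator on the compartment grid
#'
#' Second-difference diffusion coupling for one species over `N`
#' compartments of uniform length `l`. Interior compartments receive
#' `D (c[i+1] - 2 c[i] + c[i-1]) / l^2`; the end compartments the
#' one-sided reflecting forms `D (c[2] - c[1]) / l^2` and
#' `D (c[N-1] - c[N]) / l^2`, so the operator conserves total amount
#' exactly (its output sums to zero).
#'
#' @param c per-compartment concentrations (length `N >= 2`).
#' @param D diffusivity (um^2/min, >= 0).
#' @param l compartment length (um, > 0).
#' @return per-compartment rates (conc/min).
#' @export
#' @examples
#' diffusion_term(c(0, 1, 0), D = 1, l = 1)  # (1, -2, 1)
diffusion_term <- function(c, D, l) {
  if (length(c) < 2) stop("need at least 2 compartments")
  if (D < 0) stop("diffusivity must be nonnegative")
  if (l <= 0) stop("compartment length must be positive")
  as.vector(D / l^2 * .laplacian(matrix(c, nrow = 1)))
}

#' Exponential compartment growth
#'
#' New cell wall material is inserted uniformly along the long axis, so
#' each compartment grows exponentially: `l(t) = l0 exp(mu t)`. The
#' associated dilution `-mu C` is part of the reaction terms, not of
#' this geometric update.
#'
#' @param l compartment length (um, > 0).
#' @param mu growth rate (1/min, >= 0).
#' @param duration elapsed time (min).
#' @return the grown length.
#' @export
grow_step <- function(l, mu, duration) {
  if (l <= 0) stop("length must be positive")
  if (mu < 0) stop("growth rate must be nonnegative")
  l * exp(mu * duration)
}

#' Integrate the reaction-diffusion-growth system over an interval
#'
#' Advances the coupled system with a stiff implicit integrator
#' (`deSolve::lsodar`, banded numeric Jacobian; relative tolerance 1e-6,
#' absolute 1e-9). Compartment growth is applied analytically inside the
#' right-hand side. Optionally stops at the first downward crossing of a
#' threshold by the cell-average CtrA~P (the replication-initiation
#' watch); the crossing time is located by the solver's root finder.
#'
#' @param state0 initial [spatial_state()].
#' @param p parameter table.
#' @param ev cycle event state (methylation flags, compartmentalization).
#' @param t_end end of the interval (min, absolute clock).
#' @param watch optional list `list(theta = ..., after = ...)`: stop when
#'   mean CtrA~P drops below `theta`, ignoring crossings before `after`.
#' @param dt_sample sampling interval for the returned trajectory (min).
#' @param cat species catalog.
#' @return a `caulo_trajectory`: `times`, `conc` (species x compartment x
#'   time array), `l` (per-sample compartment length), `events` (the event
#'   state), and `root_time` (`NA` if no watch triggered).
#' @export
integrate_interval <- function(state0, p, ev = cycle_event_state(), t_end,
                               watch = NULL, dt_sample = 1,
                               cat = species_catalog()) {
  stopifnot(t_end > state0$t)
  ctx <- .make_context(p, cat, state0$N, S = ev$S,
                       compartmentalized = ev$compartmentalized,
                       l0 = state0$l, t0 = state0$t)
  times <- seq(state0$t, t_end, by = dt_sample)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  rootfun <- NULL
  if (!is.null(watch)) {
    after <- if (is.null(watch$after)) -Inf else watch$after
    nsp <- length(ctx$idx); ic <- ctx$idx[["CtrAp"]]
    rootfun <- function(t, y, parms) {
      m <- mean(y[seq.int(ic, by = nsp, length.out = parms$N)])
      if (t < after) 1 else m - parms$watch_theta
    }
    ctx$watch_theta <- watch$theta
  }
  out <- deSolve::lsodar(y = as.vector(state0$conc), times = times,
                         func = .rhs_core, parms = ctx,
                         rootfunc = rootfun,
                         jactype = "bandint",
                         bandup = length(ctx$idx), banddown = length(ctx$idx),
                         rtol = 1e-6, atol = 1e-9, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("solver failure at t = ", max(out[, 1]),
         "; max |state| = ", max(abs(out[nrow(out), -1])))
  tt <- out[, 1]
  nt <- length(tt)
  conc <- array(t(out[, -1, drop = FALSE]),
                dim = c(length(ctx$idx), state0$N, nt),
                dimnames = list(names(ctx$idx), NULL, NULL))
  root_time <- NA_real_
  if (!is.null(rootfun) && !is.null(attr(out, "troot")) &&
      length(attr(out, "troot")) > 0)
    root_time <- attr(out, "troot")[1]
  structure(list(times = tt,
                 conc = conc,
                 l = ctx$l0 * exp(ctx$p$mu * (tt - ctx$t0)),
                 events = ev, N = state0$N, species = names(ctx$idx),
                 root_time = root_time),
            class = "caulo_trajectory")
}

## Final spatial state of a trajectory.
.traj_end_state <- function(traj) {
  nt <- length(traj$times)
  spatial_state(traj$conc[, , nt, drop = TRUE], l = traj$l[nt],
                t = traj$times[nt])
}

#' Whole-cell totals of a protein along a trajectory
#'
#' Length-weighted whole-cell amount (sum over compartments of
#' concentration times compartment length) of a species or an aggregated
#' protein family (all phospho-states, complexes and layers), per sample
#' time. This is the quantity compared against western-blot time
#' courses.
#'
#' @param traj a `caulo_trajectory`.
#' @param what a species name or one of the aggregate names `PopZ`,
#'   `PodJL`, `PodJS`, `PodJ`, `SpmX`, `DivJ`, `PleC`, `DivL`, `CckA`,
#'   `DivK`, `DivKp`, `CpdR`, `CpdR_u`, `CtrA`, `CtrAp`.
#' @return numeric vector over `traj$times`.
#' @export
species_total <- function(traj, what) {
  members <- if (what %in% names(.totals_map)) .totals_map[[what]]
             else if (what %in% traj$species) what
             else stop("unknown species or aggregate: ", what)
  sub <- traj$conc[members, , , drop = FALSE]
  colSums(colSums(sub)) * traj$l  # sum species, sum compartments, x length
}

#' Mean concentration of a species over the cell
#' @inheritParams species_total
#' @return numeric vector over `traj$times` (length-weighted mean).
#' @export
species_mean <- function(traj, what) {
  species_total(traj, what) / (traj$N * traj$l)
}

#' Divide a predivisional cell into two daughters
#'
#' Compartments `1..N/2` (the new-pole half) become the swarmer
#' daughter, `N/2+1..N` the stalked daughter. Each half is re-gridded to
#' `N` compartments by splitting every source compartment into two equal
#' halves (piecewise-constant, amount-conserving). The swarmer daughter
#' is reoriented so that the mother's new pole becomes the daughter's
#' old pole (compartment `N`); the stalked daughter keeps the mother's
#' orientation (its old pole remains compartment `N`).
#'
#' @param predivisional a [spatial_state()] with even `N`.
#' @return list with elements `swarmer` and `stalked`, both
#'   [spatial_state()]s with `N` compartments of half the mother's
#'   compartment length.
#' @export
divide <- function(predivisional) {
  N <- predivisional$N
  if (N %% 2L != 0L) stop("division requires an even number of compartments")
  half <- N %/% 2L
  split2 <- function(m) m[, rep(seq_len(ncol(m)), each = 2), drop = FALSE]
  new_half <- predivisional$conc[, seq_len(half), drop = FALSE]
  old_half <- predivisional$conc[, seq.int(half + 1L, N), drop = FALSE]
  ## swarmer: mother's compartment 1 (new pole) -> daughter compartment N
  swarmer <- split2(new_half[, rev(seq_len(half)), drop = FALSE])
  stalked <- split2(old_half)
  l2 <- predivisional$l / 2
  list(swarmer = spatial_state(swarmer, l = l2, t = 0),
       stalked = spatial_state(stalked, l = l2, t = 0))
}

#' Packaged pseudo-initial state of a newborn swarmer cell
#'
#' Old-pole-biased PopZ polymer with inherited PodJ short form and
#' membrane-bound PleC at the same (flagellated, soon-to-be-stalked)
#' pole, uniformly high CtrA~P, and low uniform levels of the remaining
#' species. The burn-in over the first simulated cycles erases the
#' arbitrariness of these values.
#'
#' @param p parameter table.
#' @param N compartment count.
#' @param cat species catalog.
#' @return a [spatial_state()] at `t = 0`.
#' @export
initial_state <- function(p, N = 10, cat = species_catalog()) {
  pl <- .par_list(p)
  conc <- matrix(0, nrow = nrow(cat), ncol = N,
                 dimnames = list(cat$name, NULL))
  set_sp <- function(nm, x) conc[nm, ] <<- x
  old <- N  # old pole compartment
  set_sp("PopZ_m", 0.3)
  conc["PopZ_p", old] <- 3
  conc["PodJS_p", old] <- 1
  set_sp("PodJS_m", 0.02)
  conc["PleC_ph_b", old] <- 0.4
  set_sp("PleC_ph", 0.1)
  set_sp("SpmX_m", 0.05)
  set_sp("PodJL_m", 0.05)
  set_sp("DivK", 0.5)
  set_sp("DivJ", 0.05)
  set_sp("DivL", 0.3)
  set_sp("CckA_kin", 0.3)
  set_sp("CpdR_u", 0.05)
  set_sp("CpdRp", 0.4)
  set_sp("CtrA_u", 0.2)
  set_sp("CtrAp", 1.0)
  spatial_state(conc, l = pl$L_birth / N, t = 0)
}
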