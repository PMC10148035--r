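#' Cycle event state
#'
#' Discrete bookkeeping of one simulated cell cycle: the replication
#' initiation, termination, Z-ring closure, and separation times; the
#' per-gene methylation flags `S` (1 between fork passage and
#' termination, 0 otherwise); and the compartmentalization switch.
#'
#' @param S named vector of methylation flags for the four
#'   methylation-site promoters.
#' @param zring_enabled logical; whether Z-ring closure (and hence
#'   division) is scheduled. Disabled for filamenting mutants.
#' @return object of class `caulo_events`.
#' @export
cycle_event_state <- function(S = c(ctrA = 0, pleC = 0, perP = 0, podJ = 0),
                              zring_enabled = TRUE) {
  structure(list(T_ini = NA_real_, T_term = NA_real_,
                 T_zring = NA_real_, T_sep = NA_real_,
                 S = S, compartmentalized = FALSE,
                 zring_enabled = zring_enabled,
                 aborted = FALSE),
            class = "caulo_events")
}

#' Replication initiation trigger
#'
#' DNA replication initiates at the first downward crossing of the
#' threshold `theta` by the cell-average CtrA~P. Two fallback rules
#' apply: if the average is already below `theta` at `t = 15` min,
#' `T_ini = 15`; if it has never fallen below `theta` by `t = 300` min,
#' the cycle is aborted at 300 min.
#'
#' @param mean_ctra_p numeric vector of cell-average CtrA~P samples.
#' @param theta threshold (> 0).
#' @param times sample times (min), same length, strictly increasing.
#' @return a list with `status` (`"initiated"` or `"aborted"`) and
#'   `T_ini` (crossing time, linearly interpolated; `NA` when aborted).
#' @export
replication_trigger <- function(mean_ctra_p, theta, times) {
  stopifnot(theta > 0, length(mean_ctra_p) == length(times))
  i15 <- which(times >= 15)[1]
  if (!is.na(i15) && mean_ctra_p[i15] < theta)
    return(list(status = "initiated", T_ini = 15))
  eligible <- which(times >= 15 & times <= 300)
  for (i in eligible[-1]) {
    if (mean_ctra_p[i] < theta && mean_ctra_p[i - 1] >= theta) {
      f <- (mean_ctra_p[i - 1] - theta) / (mean_ctra_p[i - 1] - mean_ctra_p[i])
      return(list(status = "initiated",
                  T_ini = times[i - 1] + f * (times[i] - times[i - 1])))
    }
  }
  list(status = "aborted", T_ini = NA_real_)
}

#' Default gene coordinate table
#'
#' Positions of the four methylation-regulated genes on the circular
#' chromosome. Replication proceeds bidirectionally from the origin
#' (position 0) along two equal replichores, so the fork reaches a gene
#' after a fraction `min(coord, genome - coord) / (genome / 2)` of the
#' 90-min S phase. The shipped coordinates are package defaults chosen
#' to reproduce the observed order of fork passages (they are
#' synthetic stand-ins for annotated positions and are overridable via
#' [read_gene_coordinates()]).
#'
#' @return data frame with columns `gene`, `coordinate_bp`,
#'   `genome_length_bp`.
#' @export
default_gene_coordinates <- function() {
  data.frame(gene = c("ctrA", "pleC", "perP", "podJ"),
             coordinate_bp = c(3240000, 2531000, 1900000, 3080000),
             genome_length_bp = 4016942,
             stringsAsFactors = FALSE)
}

#' Fork-passage schedule of methylation switching
#'
#' Each methylation-site promoter becomes hemi-methylated (`S = 1`) when
#' a replication fork passes its gene, at
#' `T_ini + 90 * (distance from the origin along its replichore) /
#' (replichore length)`, and returns to the fully methylated state
#' (`S = 0`) for all genes at `T_term = T_ini + 90`.
#'
#' @param genes gene coordinate table ([default_gene_coordinates()]).
#' @param T_ini replication initiation time (min).
#' @param T_sphase S-phase duration (min, default 90).
#' @return named numeric vector of per-gene flip times.
#' @export
fork_schedule <- function(genes, T_ini, T_sphase = 90) {
  stopifnot(is.finite(T_ini))
  G <- genes$genome_length_bp
  x <- genes$coordinate_bp
  if (any(x < 0 | x > G)) stop("gene coordinate outside genome length")
  frac <- pmin(x, G - x) / (G / 2)
  ft <- T_ini + T_sphase * frac
  names(ft) <- genes$gene
  ft
}

#' Division schedule from replication termination
#'
#' Z-ring closure (compartmentalization) completes 5 min after
#' replication terminates and the daughters separate 25 min after
#' Z-ring closure. When the Z-ring is disabled (filamenting mutants)
#' no division is scheduled and the cell keeps elongating.
#'
#' @param T_term replication termination time (min).
#' @param zring_enabled logical.
#' @param zring_delay,sep_delay the two delays (min).
#' @return list with `T_zring` and `T_sep`, or `NULL` when disabled.
#' @export
division_schedule <- function(T_term, zring_enabled = TRUE,
                              zring_delay = 5, sep_delay = 25) {
  if (!zring_enabled) return(NULL)
  stopifnot(is.finite(T_term))
  list(T_zring = T_term + zring_delay,
       T_sep = T_term + zring_delay + sep_delay)
}

#' Simulate one cell cycle
#'
#' Integrates a newborn cell forward, watching the cell-average CtrA~P
#' for the replication trigger, then plays out the discrete program:
#' fork-passage methylation switching, termination, Z-ring closure
#' (diffusion blocked across the midcell interface), and separation,
#' followed by division into the two daughters. Cells that never
#' trigger initiation are integrated to 300 min and returned undivided;
#' cells with the Z-ring disabled elongate to `t_end_override`.
#'
#' @param state0 newborn [spatial_state()].
#' @param p parameter table.
#' @param genes gene coordinate table.
#' @param zring_enabled logical.
#' @param t_end_override optional simulation end for non-dividing runs
#'   (min; defaults to the `T_max` parameter).
#' @param dt_sample trajectory sampling interval (min).
#' @param cat species catalog.
#' @return a `caulo_trajectory` whose `events` record the cycle times
#'   and, when the cell divided, `daughters` (list with `swarmer`,
#'   `stalked`).
#' @export
run_cycle <- function(state0, p, genes = default_gene_coordinates(),
                      zring_enabled = TRUE, t_end_override = NULL,
                      dt_sample = 1, cat = species_catalog()) {
  pl <- .par_list(p)
  ev <- cycle_event_state(zring_enabled = zring_enabled)
  t_max <- if (is.null(t_end_override)) pl$T_max else t_end_override

  ## phase 1: to the earliest allowed initiation time
  tr <- integrate_interval(state0, p, ev, t_end = pl$T_ini_min,
                           dt_sample = dt_sample, cat = cat)
  segs <- list(tr)
  mean_ctra <- species_mean(tr, "CtrAp")
  nt <- length(tr$times)
  if (mean_ctra[nt] < pl$theta) {
    T_ini <- pl$T_ini_min
  } else {
    ## phase 2: watch for the downward theta crossing
    tr2 <- integrate_interval(.traj_end_state(tr), p, ev, t_end = pl$T_max,
                              watch = list(theta = pl$theta,
                                           after = pl$T_ini_min),
                              dt_sample = dt_sample, cat = cat)
    segs <- c(segs, list(tr2))
    T_ini <- tr2$root_time
    if (is.na(T_ini)) {
      ## never initiated: abort at 300 min (or run to the override end)
      last <- .traj_end_state(tr2)
      if (t_max > last$t) {
        tr3 <- integrate_interval(last, p, ev, t_end = t_max,
                                  dt_sample = dt_sample, cat = cat)
        segs <- c(segs, list(tr3))
      }
      ev$aborted <- TRUE
      return(.bind_trajectory(segs, ev))
    }
  }
  ev$T_ini <- T_ini
  ev$T_term <- T_ini + pl$T_sphase
  flips <- fork_schedule(genes, T_ini, pl$T_sphase)
  sched <- division_schedule(ev$T_term, zring_enabled,
                             pl$T_zring_delay, pl$T_sep_delay)
  if (!is.null(sched)) { ev$T_zring <- sched$T_zring; ev$T_sep <- sched$T_sep }

  ## phase 3: event-segmented integration to separation (or override end)
  t_stop <- if (is.null(sched)) t_max else ev$T_sep
  marks <- data.frame(time = c(unname(flips), ev$T_term,
                               if (!is.null(sched)) ev$T_zring),
                      what = c(paste0("flip_", names(flips)), "term",
                               if (!is.null(sched)) "zring"),
                      stringsAsFactors = FALSE)
  marks <- marks[marks$time < t_stop, , drop = FALSE]
  marks <- marks[order(marks$time), , drop = FALSE]
  cur <- .traj_end_state(segs[[length(segs)]])
  for (k in seq_len(nrow(marks) + 1L)) {
    t_next <- if (k <= nrow(marks)) marks$time[k] else t_stop
    if (t_next > cur$t + 1e-9) {
      trk <- integrate_interval(cur, p, ev, t_end = t_next,
                                dt_sample = dt_sample, cat = cat)
      segs <- c(segs, list(trk))
      cur <- .traj_end_state(trk)
    }
    if (k <= nrow(marks)) {
      w <- marks$what[k]
      if (startsWith(w, "flip_")) ev$S[[sub("flip_", "", w)]] <- 1
      if (w == "term") ev$S[] <- 0
      if (w == "zring") ev$compartmentalized <- TRUE
    }
  }
  traj <- .bind_trajectory(segs, ev)
  if (!is.null(sched)) traj$daughters <- divide(cur)
  traj
}

## Concatenate trajectory segments (dropping duplicated joint samples).
.bind_trajectory <- function(segs, ev) {
  times <- segs[[1]]$times; conc <- segs[[1]]$conc; l <- segs[[1]]$l
  for (s in segs[-1]) {
    keep <- s$times > times[length(times)] + 1e-9
    times <- c(times, s$times[keep])
    conc <- array(c(conc, s$conc[, , keep, drop = FALSE]),
                  dim = c(dim(conc)[1:2], length(times)))
    l <- c(l, s$l[keep])
  }
  dimnames(conc) <- list(segs[[1]]$species, NULL, NULL)
  structure(list(times = times, conc = conc, l = l, events = ev,
                 N = segs[[1]]$N, species = segs[[1]]$species,
                 root_time = NA_real_),
            class = "caulo_trajectory")
}

#' Simulate consecutive cell cycles of a strain
#'
#' Applies a mutation specification, starts from the packaged
#' pseudo-initial newborn swarmer state, and chains cycles by feeding
#' each swarmer daughter into the next cycle. By convention the fifth
#' cycle is the reporting cycle, by which time the repetitive sequence
#' of cell-cycle events has stabilized. A strain that never initiates
#' replication returns its single (undivided) trajectory.
#'
#' @param strain a [mutation_spec()] or a strain name from
#'   [strain_catalog()]; `"WT"` for wild type.
#' @param p parameter table.
#' @param n_cycles number of chained cycles (default 5).
#' @param N compartment count.
#' @param genes gene coordinate table.
#' @param dt_sample sampling interval (min).
#' @return list of `caulo_trajectory`, one per simulated cycle (a single
#'   trajectory when the strain aborts or filaments).
#' @export
run_strain <- function(strain = "WT", p = default_parameters(),
                       n_cycles = 5, N = 10,
                       genes = default_gene_coordinates(), dt_sample = 1) {
  if (is.character(strain)) strain <- strain_catalog()[[strain]]
  if (is.null(strain)) stop("unknown strain")
  mp <- apply_mutation(p, strain)
  cat <- species_catalog()
  state <- initial_state(mp$params, N, cat)
  t_override <- strain$sim_duration_override
  out <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    traj <- run_cycle(state, mp$params, genes = genes,
                      zring_enabled = mp$zring_enabled,
                      t_end_override = t_override,
                      dt_sample = dt_sample, cat = cat)
    out[[cyc]] <- traj
    if (is.null(traj$daughters)) return(out[seq_len(cyc)])
    state <- traj$daughters$swarmer
  }
  out
}
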