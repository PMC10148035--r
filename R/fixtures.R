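#' Generate pseudo-experimental calibration series
#'
#' Simulates a wild-type cell at the reference parameters and samples
#' whole-cell protein totals at the canonical time-point counts (9 for
#' PodJL, 9 for PodJS, 8 for total CtrA), evenly spaced over each of
#' cycles 2 and 3. Each series is normalized by its maximum and
#' perturbed with multiplicative lognormal noise of the given
#' coefficient of variation. These series stand in for digitized
#' western-blot time courses, so every calibration stage is testable
#' without external data.
#'
#' @param reference parameter table used as ground truth.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 for noise-free self-consistent data).
#' @param rng_seed integer RNG seed.
#' @param N compartment count for the reference simulation.
#' @param dt_sample sampling interval (min).
#' @param cycles optional precomputed list of wild-type cycle
#'   trajectories (at least three) to sample instead of re-simulating.
#' @return list of [experimental_series()] (PodJL, PodJS, total CtrA)
#'   with per-cycle values for cycles 2 and 3 and the standard weights
#'   (80, 80, 400).
#' @export
generate_fixture_data <- function(reference, noise_cv = 0, rng_seed = 1,
                                  N = 4, dt_sample = 2, cycles = NULL) {
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (is.null(cycles))
    cycles <- run_strain("WT", reference, n_cycles = 3, N = N,
                         dt_sample = dt_sample)
  if (length(cycles) < 3)
    stop("reference simulation did not complete three cycles")
  set.seed(rng_seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  spec <- list(PodJL = c(n = 9, w = 80), PodJS = c(n = 9, w = 80),
               CtrA = c(n = 8, w = 400))
  out <- list()
  for (protein in names(spec)) {
    n <- spec[[protein]][["n"]]
    ## one shared time grid for both cycles, spanning cycle 2
    frac <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    times <- frac * diff(range(cycles[[2]]$times))
    vals <- list()
    for (cyc in c(2, 3)) {
      x <- .sim_at_times(cycles[[cyc]], protein, times)
      y <- normalize_series(x)
      if (noise_cv > 0)
        y <- y * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      vals[[paste0("cycle", cyc)]] <- y
    }
    out[[protein]] <- experimental_series(protein, times, vals,
                                          weight = spec[[protein]][["w"]])
  }
  out
}
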