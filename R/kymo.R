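#' Extract a kymograph from a trajectory
#'
#' Position-by-time heatmap matrix of a species (or aggregated protein
#' family), scaled to a per-species maximum of 1. Rows are compartments
#' mapped to positions from the old pole (-1) to the new pole (+1);
#' columns are sample times. The replication-initiation and
#' compartmentalization times are carried as annotations.
#'
#' @param traj a `caulo_trajectory`.
#' @param species a species name or aggregate accepted by
#'   [species_total()].
#' @return object of class `caulo_kymograph`: `values` (compartment x
#'   time, max 1), `times`, `y` (position mapping), `species`,
#'   `annotations` (named event times).
#' @export
export_kymograph <- function(traj, species) {
  members <- if (species %in% names(.totals_map)) .totals_map[[species]]
             else if (species %in% traj$species) species
             else stop("unknown species: ", species)
  prof <- apply(traj$conc[members, , , drop = FALSE], c(2, 3), sum)
  m <- max(prof)
  if (m > 0) prof <- prof / m
  N <- traj$N
  ## compartment 1 = new pole (+1) ... compartment N = old pole (-1)
  y <- rev(seq(-1 + 1 / N, 1 - 1 / N, length.out = N))
  structure(list(values = prof, times = traj$times, y = y,
                 species = species,
                 annotations = c(T_ini = traj$events$T_ini,
                                 T_zring = traj$events$T_zring)),
            class = "caulo_kymograph")
}

#' Detect the onset of a polar focus
#'
#' First time at which the polar compartment's value exceeds twice the
#' central-compartment mean and remains above that threshold for at
#' least the persistence window. Invariant to global rescaling of the
#' kymograph.
#'
#' @param k a `caulo_kymograph`.
#' @param pole `"new"` or `"old"`.
#' @param ratio polar/central threshold (default 2).
#' @param persistence minimum time above threshold (min, default 5).
#' @return onset time in min, or `NA` if no persistent focus forms.
#' @export
detect_focus_onset <- function(k, pole = c("new", "old"), ratio = 2,
                               persistence = 5) {
  pole <- match.arg(pole)
  N <- nrow(k$values)
  polar <- if (pole == "new") k$values[1, ] else k$values[N, ]
  central <- colMeans(k$values[2:(N - 1), , drop = FALSE])
  above <- polar > ratio * central & central >= 0
  above[central == 0 & polar == 0] <- FALSE
  tt <- k$times
  i <- 1L
  n <- length(tt)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (tt[j] - tt[i] >= persistence) return(tt[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_real_
}

#' Export a trajectory as a long-format data frame
#'
#' One row per (time, compartment, species) with the concentration and
#' compartment length; suitable for CSV export and plotting.
#'
#' @param traj a `caulo_trajectory`.
#' @param species optional subset of species names.
#' @return data frame with columns `time`, `compartment`, `species`,
#'   `concentration`, `compartment_length`.
#' @export
trajectory_to_df <- function(traj, species = NULL) {
  if (is.null(species)) species <- traj$species
  sub <- traj$conc[species, , , drop = FALSE]
  nt <- length(traj$times)
  N <- traj$N
  data.frame(
    time = rep(traj$times, each = length(species) * N),
    compartment = rep(rep(seq_len(N), each = length(species)), times = nt),
    species = rep(species, times = N * nt),
    concentration = as.vector(sub),
    compartment_length = rep(traj$l, each = length(species) * N),
    stringsAsFactors = FALSE)
}
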