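#' Write a parameter table to CSV
#'
#' Columns `name, value, group, lower, upper, units, description`;
#' round-trips losslessly through [read_parameter_table()].
#'
#' @param p parameter table.
#' @param path output file.
#' @export
write_parameter_table <- function(p, path) {
  utils::write.csv(as.data.frame(p)[, c("name", "value", "group", "lower",
                                        "upper", "units", "description")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter table from CSV
#'
#' @param path CSV file written by [write_parameter_table()] (or
#'   hand-edited with the same columns).
#' @param full logical; validate the 110/41 structural counts.
#' @return a `caulo_params` data frame.
#' @export
read_parameter_table <- function(path, full = TRUE) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "value", "group", "lower", "upper")
  if (!all(req %in% names(p)))
    stop("parameter table must have columns: ", paste(req, collapse = ", "))
  rownames(p) <- p$name
  class(p) <- c("caulo_params", "data.frame")
  validate_parameters(p, full = full)
  p
}

#' Write / read the species catalog
#' @param cat a catalog data frame.
#' @param path CSV file.
#' @export
write_species_catalog <- function(cat, path) {
  utils::write.csv(as.data.frame(cat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_catalog
#' @param full logical; validate the 39-entry dimension.
#' @export
read_species_catalog <- function(path, full = TRUE) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(cat) <- cat$name
  class(cat) <- c("caulo_catalog", "data.frame")
  validate_catalog(cat, full = full)
  cat
}

#' Read a gene coordinate table
#'
#' CSV with columns `gene`, `coordinate_bp`, `genome_length_bp`.
#'
#' @param path CSV file.
#' @return data frame usable by [fork_schedule()].
#' @export
read_gene_coordinates <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene", "coordinate_bp", "genome_length_bp")
  if (!all(req %in% names(g)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  g
}

#' Write / read a strain catalog as JSON
#' @param catalog named list of [mutation_spec()]s.
#' @param path JSON file.
#' @export
write_strain_catalog <- function(catalog, path) {
  enc <- lapply(catalog, function(m)
    list(name = m$name, set = as.list(m$set), scale = as.list(m$scale),
         zring_enabled = m$zring_enabled,
         sim_duration_override = m$sim_duration_override))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_strain_catalog
#' @export
read_strain_catalog <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(m)
    mutation_spec(m$name,
                  set = unlist(m$set) %||% numeric(0),
                  scale = unlist(m$scale) %||% numeric(0),
                  zring_enabled = isTRUE(m$zring_enabled),
                  sim_duration_override = m$sim_duration_override))
  names(out) <- vapply(out, function(m) m$name, "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a kymograph matrix as CSV
#'
#' Rows are compartments (with their pole-to-pole positions), columns
#' the sample times.
#'
#' @param k a `caulo_kymograph`.
#' @param path CSV file.
#' @export
write_kymograph_csv <- function(k, path) {
  m <- as.data.frame(k$values)
  names(m) <- sprintf("t%.1f", k$times)
  m <- cbind(position = k$y, m)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as long-format CSV
#' @param traj a `caulo_trajectory`.
#' @param path CSV file.
#' @param species optional subset.
#' @export
write_trajectory_csv <- function(traj, path, species = NULL) {
  utils::write.csv(trajectory_to_df(traj, species), path, row.names = FALSE)
  invisible(path)
}

#' Event log of a trajectory
#' @param traj a `caulo_trajectory`.
#' @return data frame of (event, time) rows for the recorded events.
#' @export
event_log <- function(traj) {
  ev <- traj$events
  out <- data.frame(event = c("T_ini", "T_term", "T_zring", "T_sep"),
                    time = c(ev$T_ini, ev$T_term, ev$T_zring, ev$T_sep),
                    stringsAsFactors = FALSE)
  out[!is.na(out$time), , drop = FALSE]
}
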