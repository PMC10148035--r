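#' Mutation specification
#'
#' Declarative description of a strain: parameter overrides (absolute
#' values via `set`, multipliers via `scale`), whether the Z-ring can
#' close, and an optional simulation-duration override for filamenting
#' runs.
#'
#' @param name strain identifier.
#' @param set named numeric vector of absolute parameter overrides.
#' @param scale named numeric vector of multiplicative overrides (>= 0).
#' @param zring_enabled logical.
#' @param sim_duration_override simulation end in min, or `NULL`.
#' @return object of class `caulo_mutation`.
#' @export
mutation_spec <- function(name, set = numeric(0), scale = numeric(0),
                          zring_enabled = TRUE,
                          sim_duration_override = NULL) {
  if (length(scale) && any(scale < 0)) stop("multipliers must be >= 0")
  structure(list(name = name, set = set, scale = scale,
                 zring_enabled = zring_enabled,
                 sim_duration_override = sim_duration_override),
            class = "caulo_mutation")
}

#' Shipped strain catalog
#'
#' The named mutants of the study: deletions are modeled by zeroing the
#' corresponding synthesis rate, kinase/phosphatase point mutants by
#' zeroing only the catalytic rate (binding intact), "delocalized"
#' strains by removing a scaffold-client recruitment term, and
#' overexpression strains by synthesis-rate multipliers (the shipped
#' induction factors 3x/10x/5x are package defaults).
#'
#' @return named list of [mutation_spec()]s, including `"WT"`.
#' @export
strain_catalog <- function() {
  specs <- list(
    mutation_spec("WT"),
    mutation_spec("dpodJ", set = c(k_s_PodJ = 0, k_s_PodJ2 = 0)),
    mutation_spec("dpopZ", set = c(k_s_PopZ = 0)),
    mutation_spec("dspmX", set = c(k_s_SpmX = 0)),
    mutation_spec("dspmX_filament", set = c(k_s_SpmX = 0),
                  zring_enabled = FALSE, sim_duration_override = 750),
    mutation_spec("ddivJ", set = c(k_s_DivJ = 0)),
    mutation_spec("divJ_H338A", set = c(k_ph_DivJ = 0)),
    mutation_spec("dpleC", set = c(k_s_PleC = 0)),
    mutation_spec("pleC_H610A", set = c(k_cat_PleC = 0, k_kin_PleC = 0)),
    mutation_spec("pleC_F778L", set = c(k_kin_PleC = 0)),
    mutation_spec("delocalized_PleC", set = c(k_fb_PleC = 0)),
    mutation_spec("delocalized_DivL", set = c(alpha_DivLPodJ = 0)),
    mutation_spec("PodJ_op1", scale = c(k_s_PodJ = 3, k_s_PodJ2 = 3)),
    mutation_spec("PodJ_op2", scale = c(k_s_PodJ = 10, k_s_PodJ2 = 10)),
    mutation_spec("PopZ_op", scale = c(k_s_PopZ = 5))
  )
  names(specs) <- vapply(specs, function(s) s$name, "")
  specs
}

#' Apply a mutation to a parameter set
#'
#' Pure function: returns a modified copy of the parameter table plus
#' the strain's structural flags; the input is never altered.
#'
#' @param p parameter table.
#' @param m a [mutation_spec()].
#' @return list with `params` (modified table), `zring_enabled`, and
#'   `sim_duration_override`.
#' @export
apply_mutation <- function(p, m) {
  stopifnot(inherits(m, "caulo_mutation"))
  q <- p
  if (length(m$set)) q <- set_params(q, m$set)
  if (length(m$scale)) {
    i <- match(names(m$scale), q$name)
    if (anyNA(i)) stop("unknown parameter: ",
                       paste(names(m$scale)[is.na(i)], collapse = ", "))
    newv <- q$value[i] * unname(m$scale)
    names(newv) <- names(m$scale)
    q <- set_params(q, newv)
  }
  list(params = q, zring_enabled = m$zring_enabled,
       sim_duration_override = m$sim_duration_override)
}

## Time- and length-weighted mean of total DivK~P (free + bound +
## complexed) over a trajectory's reporting window.
.divkp_window_mean <- function(traj) {
  tot <- species_total(traj, "DivKp")          # whole-cell amount per sample
  vol <- traj$N * traj$l                        # cell length per sample
  ## time average of the cell-average concentration, trapezoidal
  conc <- tot / vol
  tt <- traj$times
  sum(diff(tt) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2) /
    diff(range(tt))
}

#' Mutant DivK~P level relative to wild type
#'
#' Ratio of the time- and length-weighted mean of total DivK~P (free
#' plus membrane-bound plus complexed) over the mutant's reporting
#' window to the same quantity in the wild-type reporting cycle: the
#' normalized phosphorylation statistic of the mutant comparison table.
#'
#' @param mutant_traj,wt_traj `caulo_trajectory` objects covering the
#'   respective reporting windows.
#' @return dimensionless ratio.
#' @export
mutant_divkp_ratio <- function(mutant_traj, wt_traj) {
  wt <- .divkp_window_mean(wt_traj)
  if (wt <= 0) stop("wild-type DivK~P mean is zero")
  .divkp_window_mean(mutant_traj) / wt
}

#' Reporting trajectory of a strain simulation
#'
#' The fifth (or last completed) cycle for strains that divide; the
#' single 0-300 min (or overridden-duration) trajectory otherwise.
#'
#' @param cycles list returned by [run_strain()].
#' @return a `caulo_trajectory`.
#' @export
reporting_cycle <- function(cycles) cycles[[length(cycles)]]
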