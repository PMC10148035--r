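#' Default parameter table
#'
#' Returns the full table of the 110 named rate constants, affinities,
#' diffusivities, and timing constants of the model. Parameters are
#' partitioned into a `fixed` group (69 entries: physical constants,
#' timing of the replication/division program, diffusivities, and
#' binding/unbinding rates taken as structural) and an `estimated` group
#' (41 entries: the scaffold polymerization kinetics, scaffold-client
#' recruitment strengths, catalytic rates of the phosphorelay, CtrA
#' synthesis/proteolysis, and the replication threshold), which is the
#' group the evolutionary calibration searches. Bounds on the estimated
#' group default to 0.4x and 1.5x of the tabulated value, the window used
#' when reseeding a calibration round.
#'
#' Units: time in minutes, length in micrometers, concentrations in
#' dimensionless scaled units. Diffusivities are stored in um^2/min.
#'
#' @return A data frame of class `caulo_params` with columns `name`,
#'   `value`, `group`, `lower`, `upper`, `units`, `description`.
#' @export
#' @examples
#' p <- default_parameters()
#' table(p$group)  # 69 fixed, 41 estimated
default_parameters <- function() {
  E <- "estimated"; X <- "fixed"
  def <- function(name, value, group, units, description) {
    data.frame(name = name, value = value, group = group,
               lower = if (group == "estimated") 0.4 * value else 0,
               upper = if (group == "estimated") 1.5 * value else Inf,
               units = units, description = description,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    ## ---- global physical & timing constants -------------------------
    def("mu",           log(4.4 / 2) / 150, X, "1/min",
        "exponential growth rate, from 2 um at birth to 4.4 um at 150 min"),
    def("L_birth",      2,    X, "um",    "cell length at birth"),
    def("T_sphase",     90,   X, "min",   "duration of chromosome replication (S phase)"),
    def("T_zring_delay", 5,   X, "min",   "Z-ring closure delay after replication termination"),
    def("T_sep_delay",  25,   X, "min",   "cell separation delay after Z-ring closure"),
    def("T_ini_min",    15,   X, "min",   "earliest allowed replication initiation"),
    def("T_max",        300,  X, "min",   "simulation cutoff when initiation never triggers"),
    def("alpha_D",      4300, X, "um^2/s kDa^2", "mass-law diffusivity coefficient"),
    def("D0",           0.65, X, "um^2/s", "mass-law diffusivity offset"),
    def("polar_boost",  1.25, X, "-",     "polar enhancement of PopZ/PodJ autocatalysis"),
    def("theta",        0.30, E, "conc",  "CtrA~P threshold for replication initiation"),
    def("eps_meth",     0.05, E, "-",     "transcriptional leak of fully methylated promoters"),
    ## ---- Hill exponents ---------------------------------------------
    def("n_PodJ", 4, X, "-", "Hill exponent, CtrA~P inhibition of podJ"),
    def("n_CtrA", 2, X, "-", "Hill exponent, CtrA~P regulation of ctrA P1/P2"),
    def("alpha_SpmXPodJ", 1, X, "1/conc",
        "PodJ polymer inhibition of SpmX nucleation (polar exclusion)"),
    ## ---- PopZ activator-substrate-depletion kinetics ----------------
    def("k_s_PopZ",      0.030,  E, "conc/min", "PopZ synthesis rate (central compartments)"),
    def("k_d_PopZ",      0.010,  E, "1/min",    "PopZ degradation rate"),
    def("k_depol_PopZ",  0.03,   E, "1/min",    "PopZ depolymerization rate"),
    def("k_dnv_PopZ",    0.04, E, "1/min",    "PopZ de novo polymerization rate"),
    def("k_aut_PopZ",    0.8,    E, "1/(conc^2 min)", "PopZ autocatalytic polymerization rate"),
    def("alpha_PopZPodJ", 60,     E, "1/conc",   "PodJ enhancement of PopZ de novo polymerization"),
    def("D_PopZ_p",      0.01,   X, "um^2/min", "PopZ polymer diffusivity"),
    ## ---- PodJ long form ----------------------------------------------
    def("k_s_PodJ",      0.010,  E, "conc/min", "PodJL methylation-gated synthesis rate"),
    def("k_s_PodJ2",     0.030,  E, "conc/min", "PodJL CtrA~P-inhibited synthesis rate"),
    def("k_d_PodJ1",     0.008,  E, "1/min",    "PodJL basal degradation rate"),
    def("k_d_PodJ2",     0.60,   E, "1/(conc min)", "PerP-dependent truncation of PodJL into PodJS"),
    def("k_depol_PodJ",  0.08,   E, "1/min",    "PodJL depolymerization rate"),
    def("k_dnv_PodJ",    0.01, E, "1/min",    "PodJL de novo polymerization rate"),
    def("k_aut_PodJ",    2.5,    E, "1/(conc^2 min)", "PodJL autocatalytic polymerization rate"),
    def("alpha_PodJSpmX", 1,     E, "1/conc",   "SpmX inhibition of PodJL polymerization"),
    def("J_i_PodJCtrA",  0.30,   E, "conc",     "CtrA~P dissociation constant at the podJ promoter"),
    def("D_PodJL_p",     0.01,   X, "um^2/min", "PodJL polymer diffusivity"),
    ## ---- PodJ short form ---------------------------------------------
    def("k_d_PodJS",     0.05,  E, "1/min",    "PodJS degradation rate"),
    def("k_depol_PodJS", 0.08,   X, "1/min",    "PodJS depolymerization rate"),
    def("k_dnv_PodJS",   0.0002, X, "1/min",    "PodJS de novo polymerization rate"),
    def("k_aut_PodJS",   1.2,    X, "1/(conc^2 min)", "PodJS autocatalytic polymerization rate"),
    def("D_PodJS_p",     0.01,   X, "um^2/min", "PodJS polymer diffusivity"),
    ## ---- SpmX ---------------------------------------------------------
    def("k_s_SpmX",      0.010,  E, "conc/min", "SpmX synthesis rate"),
    def("k_d_SpmX",      0.004,  E, "1/min",    "SpmX degradation rate"),
    def("k_depol_SpmX",  0.08,   E, "1/min",    "SpmX depolymerization rate"),
    def("k_dnv_SpmX",    0.002, E, "1/min",    "SpmX de novo polymerization rate"),
    def("k_aut_SpmX",    3,    E, "1/(conc^2 min)", "SpmX autocatalytic polymerization rate"),
    def("alpha_SpmXPopZ", 40,     E, "1/conc",   "PopZ polymer enhancement of SpmX nucleation"),
    def("D_SpmX_p",      0.01,   X, "um^2/min", "SpmX polymer diffusivity"),
    ## ---- PerP ---------------------------------------------------------
    def("k_s_PerP",      0.3,   E, "conc/min", "PerP synthesis rate (methylation- and CtrA~P-gated)"),
    def("k_d_PerP",      0.05,   X, "1/min",    "PerP degradation rate"),
    def("J_a_PerPCtrA",  0.40,   E, "conc",     "CtrA~P dissociation constant at the perP promoter"),
    ## ---- DivK ---------------------------------------------------------
    def("k_s_DivK",      0.012,  X, "conc/min", "DivK synthesis rate"),
    def("k_d_DivK",      0.010,  X, "1/min",    "DivK degradation rate"),
    def("k_on_DivK",     0.02,   X, "1/min",    "DivK basal polar binding rate"),
    def("k_off_DivK",    0.20,   X, "1/min",    "DivK polar unbinding rate"),
    def("k_fb_DivK",     5,      X, "1/conc",   "PopZ polymer enhancement of DivK polar binding"),
    def("D_b_DivK",      0.01,   X, "um^2/min", "diffusivity of membrane-bound DivK forms"),
    ## ---- DivJ ---------------------------------------------------------
    def("k_s_DivJ",      0.006,  X, "conc/min", "DivJ synthesis rate"),
    def("k_d_DivJ",      0.005,  X, "1/min",    "DivJ degradation rate"),
    def("k_on_DivJ",     0.05,   X, "1/min",    "DivJ basal polar binding rate"),
    def("k_off_DivJ",    0.30,   X, "1/min",    "DivJ polar unbinding rate"),
    def("k_fb_DivJ",     100,     E, "1/conc",   "SpmX polymer enhancement of DivJ polar binding"),
    def("k_bind_DivJDivK",    4,   X, "1/(conc min)", "DivJ + DivK association"),
    def("k_unbind_DivJDivK",  0.5, X, "1/min",  "DivJ:DivK dissociation"),
    def("k_bind_DivJDivKp",   2,   X, "1/(conc min)", "DivJ + DivK~P association"),
    def("k_unbind_DivJDivKp", 0.5, X, "1/min",  "DivJ:DivK~P dissociation"),
    def("k_ph_DivJ",     3,      E, "1/min",    "phosphotransfer within DivJ:DivK (kinase step)"),
    def("D_b_DivJ",      0.01,   X, "um^2/min", "diffusivity of membrane-bound DivJ forms"),
    ## ---- PleC ---------------------------------------------------------
    def("k_s_PleC",      0.12,  X, "conc/min", "PleC synthesis rate (methylation-gated)"),
    def("k_d_PleC",      0.025,  X, "1/min",    "PleC degradation rate"),
    def("k_on_PleC",     0.02,   X, "1/min",    "PleC basal polar binding rate"),
    def("k_off_PleC",    0.30,   X, "1/min",    "PleC polar unbinding rate"),
    def("k_fb_PleC",     20,     E, "1/conc",   "PodJ polymer enhancement of PleC polar binding"),
    def("k_bind_PleCDivKp",   4,   X, "1/(conc min)", "PleC + DivK~P association"),
    def("k_unbind_PleCDivKp", 0.5, X, "1/min",  "PleC:DivK~P dissociation"),
    def("k_cat_PleC",    20,      E, "1/min",    "PleC phosphatase catalysis (DivK~P -> DivK)"),
    def("k_sw_PleC",     0.3,    E, "1/min",    "PleC:DivK~P switch to kinase conformation"),
    def("k_rx_PleC",     1,      X, "1/min",    "PleC kinase relaxation back to phosphatase"),
    def("k_kin_PleC",    0.3,    E, "1/(conc min)", "PleC kinase phosphorylation of DivK"),
    def("D_b_PleC",      0.01,   X, "um^2/min", "diffusivity of membrane-bound PleC forms"),
    ## ---- DivL ---------------------------------------------------------
    def("k_s_DivL",      0.008,  X, "conc/min", "DivL synthesis rate"),
    def("k_d_DivL",      0.005,  X, "1/min",    "DivL degradation rate"),
    def("k_on_DivL",     0.02,   X, "1/min",    "DivL basal polar binding rate"),
    def("k_off_DivL",    0.30,   X, "1/min",    "DivL polar unbinding rate"),
    def("alpha_DivLPodJ", 15,    E, "1/conc",   "PodJ polymer enhancement of DivL polar binding"),
    def("k_fb_DivLPopZ", 3,      X, "1/conc",   "PopZ polymer enhancement of DivL polar binding"),
    def("k_bind_DivLDivKp",   1,   X, "1/(conc min)", "DivL + DivK~P association"),
    def("k_unbind_DivLDivKp", 1, X, "1/min",  "DivL:DivK~P dissociation"),
    def("D_b_DivL",      0.01,   X, "um^2/min", "diffusivity of membrane-bound DivL forms"),
    ## ---- CckA ---------------------------------------------------------
    def("k_s_CckA",      0.010,  X, "conc/min", "CckA synthesis rate"),
    def("k_d_CckA",      0.005,  X, "1/min",    "CckA degradation rate"),
    def("k_on_CckA",     0.02,   X, "1/min",    "CckA basal polar binding rate"),
    def("k_off_CckA",    0.30,   X, "1/min",    "CckA polar unbinding rate"),
    def("k_fb_CckA",     20,     E, "1/conc",   "bound-DivL enhancement of CckA polar binding"),
    def("k_fb_CckAPopZ", 2,      X, "1/conc",   "PopZ polymer enhancement of CckA polar binding"),
    def("k_kp_CckA",     10,      E, "1/(conc min)", "DivL:DivK~P-driven CckA kinase-to-phosphatase switch"),
    def("k_pk_CckA",     0.6,    E, "1/min",    "basal CckA phosphatase-to-kinase relaxation"),
    def("k_ph_CtrA",     3,      E, "1/(conc min)", "CckA kinase phosphorylation of CtrA"),
    def("k_deph_CtrA",   6,      X, "1/(conc min)", "CckA phosphatase dephosphorylation of CtrA~P"),
    def("k_ph_CpdR",     6,      X, "1/(conc min)", "CckA kinase phosphorylation of CpdR"),
    def("k_deph_CpdR",   6,      X, "1/(conc min)", "CckA phosphatase dephosphorylation of CpdR~P"),
    def("D_b_CckA",      0.01,   X, "um^2/min", "diffusivity of membrane-bound CckA forms"),
    ## ---- CpdR ---------------------------------------------------------
    def("k_s_CpdR",      0.010,  X, "conc/min", "CpdR synthesis rate"),
    def("k_d_CpdR",      0.010,  X, "1/min",    "CpdR degradation rate"),
    def("k_on_CpdR",     0.02,   X, "1/min",    "CpdR basal polar binding rate"),
    def("k_off_CpdR",    0.30,   X, "1/min",    "CpdR polar unbinding rate"),
    def("k_fb_CpdR",     10,     E, "1/conc",   "PopZ polymer enhancement of CpdR polar binding"),
    def("D_b_CpdR",      0.01,   X, "um^2/min", "diffusivity of membrane-bound CpdR forms"),
    ## ---- CtrA ---------------------------------------------------------
    def("k_s_CtrA1",     0.060,  E, "conc/min", "CtrA synthesis from the weak P1 promoter (CtrA~P-inhibited)"),
    def("k_s_CtrA2",     0.120,  E, "conc/min", "CtrA synthesis from the strong P2 promoter (CtrA~P-activated)"),
    def("k_d_CtrA",      0.002,  X, "1/min",    "CtrA basal degradation rate"),
    def("k_deg_CtrA",    0.6,    E, "1/(conc min)", "CpdR(u)-dependent proteolysis of both CtrA forms"),
    def("J_i_CtrAP",     0.30,   X, "conc",     "CtrA~P dissociation constant at ctrA P1"),
    def("J_a_CtrAP",     0.40,   X, "conc",     "CtrA~P dissociation constant at ctrA P2")
  )
  p <- do.call(rbind, rows)
  rownames(p) <- p$name
  class(p) <- c("caulo_params", "data.frame")
  p
}

#' Validate a parameter table
#'
#' Checks that all values are nonnegative and within their bounds, names
#' are unique, and (for the full model) the table holds exactly 110
#' parameters of which 41 are in the estimated group.
#'
#' @param p a parameter table as returned by [default_parameters()].
#' @param full logical; enforce the 110/41 structural counts.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_parameters <- function(p, full = TRUE) {
  stopifnot(is.data.frame(p),
            all(c("name", "value", "group", "lower", "upper") %in% names(p)))
  if (anyDuplicated(p$name) > 0L) stop("parameter names must be unique")
  if (any(p$value < 0)) stop("parameter values must be nonnegative")
  if (any(p$value < p$lower - 1e-12 | p$value > p$upper + 1e-12))
    stop("parameter values must lie within their bounds")
  if (!all(p$group %in% c("fixed", "estimated")))
    stop("group must be 'fixed' or 'estimated'")
  if (full) {
    if (nrow(p) != 110L)
      stop("full model requires exactly 110 parameters, got ", nrow(p))
    if (sum(p$group == "estimated") != 41L)
      stop("full model requires exactly 41 estimated parameters, got ",
           sum(p$group == "estimated"))
  }
  invisible(TRUE)
}

## Fast named-list view of a parameter table, used inside the RHS.
.par_list <- function(p) {
  v <- as.list(p$value)
  names(v) <- p$name
  v
}

#' Look up a parameter value
#' @param p parameter table.
#' @param name parameter name.
#' @return the numeric value.
#' @export
param_value <- function(p, name) {
  i <- match(name, p$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  p$value[i]
}

#' Set parameter values
#'
#' Returns a modified copy; the input table is never altered.
#'
#' @param p parameter table.
#' @param values named numeric vector of replacement values.
#' @return a new parameter table.
#' @export
set_params <- function(p, values) {
  i <- match(names(values), p$name)
  if (anyNA(i)) stop("unknown parameter: ",
                     paste(names(values)[is.na(i)], collapse = ", "))
  p$value[i] <- unname(values)
  ## widen bounds for explicit overrides (e.g. mutants set rates to 0)
  p$lower[i] <- pmin(p$lower[i], p$value[i])
  p$upper[i] <- pmax(p$upper[i], p$value[i])
  p
}
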