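#' Simulate the isolated PopZ activator-substrate-depletion subsystem
#'
#' Integrates only the PopZ monomer/polymer pair on a fixed grid:
#' uniform synthesis of monomer in every compartment, degradation and
#' dilution, de novo and autocatalytic polymerization, depolymerization,
#' and no-flux diffusion with the fast monomer / slow polymer contrast.
#' This is the minimal two-field Turing system of the model, used to
#' demonstrate that the polymerization kinetics amplify a small polar
#' bias into a polar polymer focus while an exactly uniform state stays
#' uniform.
#'
#' @param p parameter table (PopZ entries and `mu`, `alpha_D`, `D0` used).
#' @param N compartment count.
#' @param l compartment length (um; fixed, no growth).
#' @param t_end integration time (min).
#' @param perturb relative polymer excess seeded in the old-pole
#'   compartment (e.g. 0.01 for 1%; 0 for an exactly uniform start).
#' @param m0,p0 initial uniform monomer / polymer concentrations;
#'   defaults to the uniform steady state found numerically.
#' @return list with `times`, `m`, `p` (compartment x time matrices).
#' @export
run_popz_subsystem <- function(p, N = 10, l = 0.2, t_end = 400,
                               perturb = 0.01, m0 = NULL, p0 = NULL) {
  pl <- .par_list(p)
  Dm <- 60 * diffusion_coefficient(19.2, pl$alpha_D, pl$D0)
  Dp <- pl$D_PopZ_p
  loss <- pl$k_d_PopZ + pl$mu
  if (is.null(m0) || is.null(p0)) {
    ## uniform steady state: total fixed by synthesis/decay balance,
    ## polymer share by the polymerization equilibrium
    tot <- pl$k_s_PopZ / loss
    f <- function(pp) {
      mm <- tot - pp
      pl$k_dnv_PopZ * mm + pl$k_aut_PopZ * mm * pp^2 -
        (loss + pl$k_depol_PopZ) * pp
    }
    pp <- stats::uniroot(f, c(1e-9, tot - 1e-9))$root
    m0 <- tot - pp; p0 <- pp
  }
  y0 <- c(rep(m0, N), rep(p0, N))
  y0[2 * N] <- y0[2 * N] * (1 + perturb)   # old-pole polymer excess
  rhs <- function(t, y, parms) {
    m <- y[1:N]; pp <- y[(N + 1):(2 * N)]
    dnv <- pl$k_dnv_PopZ * m
    aut <- pl$k_aut_PopZ * m * pp^2
    dm <- pl$k_s_PopZ - loss * m + pl$k_depol_PopZ * pp - dnv - aut +
      as.vector(Dm / l^2 * .laplacian(matrix(m, nrow = 1)))
    dp <- -loss * pp - pl$k_depol_PopZ * pp + dnv + aut +
      as.vector(Dp / l^2 * .laplacian(matrix(pp, nrow = 1)))
    list(c(dm, dp))
  }
  times <- seq(0, t_end, by = 2)
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  list(times = out[, 1],
       m = t(out[, 2:(N + 1), drop = FALSE]),
       p = t(out[, (N + 2):(2 * N + 1), drop = FALSE]))
}
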