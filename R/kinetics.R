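#' Hill activation function
#'
#' Fractional promoter activity under transcriptional activation by a
#' regulator (in this model, CtrA~P): `x^n / (J^n + x^n)`.
#'
#' @param x regulator concentration (>= 0).
#' @param J dissociation constant (> 0).
#' @param n Hill exponent (>= 1).
#' @return activation fraction in `[0, 1]`, strictly increasing in `x`.
#' @export
#' @examples
#' hill_activation(1, 1, 2)  # half-maximal at x = J
hill_activation <- function(x, J, n) {
  if (any(x < 0)) stop("regulator concentration must be nonnegative")
  if (any(J <= 0)) stop("dissociation constant must be positive")
  if (any(n < 1)) stop("Hill exponent must be >= 1")
  r <- (x / J)^n
  r / (1 + r)
}

#' Hill inhibition function
#'
#' Fractional promoter activity under transcriptional inhibition:
#' `J^n / (J^n + x^n)`. Complements [hill_activation()] so that the two
#' sum to one at equal `(x, J, n)`.
#'
#' @inheritParams hill_activation
#' @return inhibition fraction in `[0, 1]`, strictly decreasing in `x`.
#' @export
hill_inhibition <- function(x, J, n) {
  1 - hill_activation(x, J, n)
}

#' Methylation factor for gene expression
#'
#' Promoters carrying a methylation site (ctrA, pleC, perP, podJ)
#' transcribe at a reduced, leaky rate while fully methylated (`S = 0`)
#' and at full rate once the replication fork has passed and left them
#' hemi-methylated (`S = 1`). The synthesis multiplier is
#' `(1 - eps) * S + eps`.
#'
#' @param S binary methylation state (0 fully methylated, 1 hemi-methylated).
#' @param eps leak fraction in `(0, 1]`.
#' @return multiplier in `[eps, 1]`.
#' @export
methylation_factor <- function(S, eps) {
  if (any(!(S %in% c(0, 1)))) stop("methylation state must be 0 or 1")
  if (any(eps <= 0 | eps > 1)) stop("leak fraction must be in (0, 1]")
  (1 - eps) * S + eps
}

#' Diffusion coefficient of a monomeric protein
#'
#' Empirical mass law for cytosolic protein diffusion,
#' `D = alpha / mw^2 + D0` with `alpha = 4.3e3 um^2 s^-1 kDa^2` and
#' `D0 = 0.65 um^2 s^-1`. Applies to monomeric (cytosolic) species only;
#' polymer and membrane-bound diffusivities are separate small parameters.
#'
#' @param mw molecular weight in kDa (> 0).
#' @param alpha,D0 law constants; defaults as above.
#' @return diffusivity in um^2 s^-1, monotonically decreasing in `mw`.
#' @export
#' @examples
#' diffusion_coefficient(100)  # 1.08 um^2/s
diffusion_coefficient <- function(mw, alpha = 4.3e3, D0 = 0.65) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  alpha / mw^2 + D0
}

#' PopZ reaction terms of the activator-substrate-depletion pair
#'
#' Rate of change of PopZ monomer (substrate) and polymer (activator)
#' from the local reaction terms: degradation and dilution `-(k_d + mu)`,
#' depolymerization, de novo polymerization enhanced by total long-form
#' PodJ, and autocatalytic polymerization `k_aut * m * p^2` whose rate
#' constant is 25% larger in polar compartments. Synthesis and diffusion
#' are handled by the full right-hand side, not here.
#'
#' @param popz_m,popz_p PopZ monomer / polymer concentrations (>= 0).
#' @param podjl_total total long-form PodJ concentration (>= 0).
#' @param p parameter table ([default_parameters()]).
#' @param polar logical; apply the polar autocatalysis boost.
#' @return named list with `rate_m` and `rate_p` (conc/min).
#' @export
popz_rates <- function(popz_m, popz_p, podjl_total, p, polar = FALSE) {
  if (any(c(popz_m, popz_p, podjl_total) < 0))
    stop("concentrations must be nonnegative")
  pl <- if (is.data.frame(p)) .par_list(p) else p
  kaut <- pl$k_aut_PopZ * ifelse(polar, pl$polar_boost, 1)
  dnv <- pl$k_dnv_PopZ * (1 + pl$alpha_PopZPodJ * podjl_total) * popz_m
  aut <- kaut * popz_m * popz_p^2
  loss_m <- (pl$k_d_PopZ + pl$mu) * popz_m
  loss_p <- (pl$k_d_PopZ + pl$mu) * popz_p
  depol <- pl$k_depol_PopZ * popz_p
  list(rate_m = -loss_m + depol - dnv - aut,
       rate_p = -loss_p - depol + dnv + aut)
}

#' Long-form PodJ reaction terms
#'
#' Rate of change of PodJL monomer and polymer. Synthesis (central
#' compartments only) combines a methylation-gated term and a CtrA~P
#' Hill-inhibited term. Loss combines basal degradation, PerP-dependent
#' truncation, and dilution; the truncation flux is a conversion, routed
#' into the short-form PodJS pool and returned in `podjs_m_src` /
#' `podjs_p_src`. Polymer exchange follows the activator-substrate
#' scheme with autocatalysis suppressed by total SpmX and boosted 25% at
#' the poles.
#'
#' @param podjl_m,podjl_p PodJL monomer / polymer concentrations (>= 0).
#' @param spmx_total total SpmX concentration (>= 0).
#' @param ctra_p local CtrA~P concentration (>= 0).
#' @param perp local PerP concentration (>= 0).
#' @param S_podJ binary methylation state of the podJ promoter.
#' @param p parameter table.
#' @param polar logical; polar compartment (no synthesis, boosted
#'   autocatalysis).
#' @return named list with `rate_m`, `rate_p`, and the conversion
#'   sources `podjs_m_src`, `podjs_p_src` feeding PodJS.
#' @export
podjl_rates <- function(podjl_m, podjl_p, spmx_total, ctra_p, perp,
                        S_podJ, p, polar = FALSE) {
  if (any(c(podjl_m, podjl_p, spmx_total, ctra_p, perp) < 0))
    stop("concentrations must be nonnegative")
  pl <- if (is.data.frame(p)) .par_list(p) else p
  syn <- if (polar) 0 else
    pl$k_s_PodJ * methylation_factor(S_podJ, pl$eps_meth) +
    pl$k_s_PodJ2 * hill_inhibition(ctra_p, pl$J_i_PodJCtrA, pl$n_PodJ)
  kloss <- pl$k_d_PodJ1 + pl$k_d_PodJ2 * perp + pl$mu
  kaut <- pl$k_aut_PodJ / (1 + pl$alpha_PodJSpmX * spmx_total) *
    ifelse(polar, pl$polar_boost, 1)
  dnv <- pl$k_dnv_PodJ * podjl_m
  aut <- kaut * podjl_m * podjl_p^2
  depol <- pl$k_depol_PodJ * podjl_p
  list(rate_m = syn - kloss * podjl_m + depol - dnv - aut,
       rate_p = -kloss * podjl_p - depol + dnv + aut,
       podjs_m_src = pl$k_d_PodJ2 * perp * podjl_m,
       podjs_p_src = pl$k_d_PodJ2 * perp * podjl_p)
}
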