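#' Spatial state constructor
#'
#' A spatial state holds the concentration of every species in each of
#' `N` compartments of a uniform grid, the per-compartment length, and
#' the clock time. Compartment 1 is the new pole, compartment `N` the
#' old pole.
#'
#' @param conc species-by-compartment concentration matrix with species
#'   row names.
#' @param l compartment length (um, uniform).
#' @param t clock time (min).
#' @return object of class `caulo_state`.
#' @export
spatial_state <- function(conc, l, t = 0) {
  stopifnot(is.matrix(conc), l > 0, ncol(conc) >= 2)
  structure(list(conc = conc, l = l, t = t, N = ncol(conc)),
            class = "caulo_state")
}

## Build the per-species diffusivity vector (um^2/min). Cytosolic species
## follow the empirical mass law (converted from um^2/s); polymers and
## membrane-bound forms use their dedicated small diffusivities.
.species_diffusivity <- function(cat, pl) {
  D <- numeric(nrow(cat))
  names(D) <- cat$name
  for (i in seq_len(nrow(cat))) {
    if (cat$layer[i] == "membrane") {
      D[i] <- pl[[paste0("D_b_", cat$family[i])]]
    } else if (cat$form[i] == "polymer") {
      D[i] <- pl[[paste0("D_", cat$name[i])]]
    } else {
      D[i] <- 60 * diffusion_coefficient(cat$mw[i], pl$alpha_D, pl$D0)
    }
  }
  D
}

## Integration context: everything the ODE right-hand side needs,
## precomputed once per integration segment.
.make_context <- function(p, cat, N, S = c(ctrA = 0, pleC = 0, perP = 0, podJ = 0),
                          compartmentalized = FALSE, l0 = NULL, t0 = 0) {
  pl <- if (is.data.frame(p)) .par_list(p) else p
  if (is.null(l0)) l0 <- pl$L_birth / N
  idx <- seq_len(nrow(cat))
  names(idx) <- cat$name
  central <- rep(1, N); central[c(1, N)] <- 0
  boost <- rep(1, N); boost[c(1, N)] <- pl$polar_boost
  ## polar membrane exchange table: free index, bound index, family,
  ## with the family's basal on/off rates resolved once
  fams <- c("DivK", "DivK", "DivJ", "DivJ", "DivJ", "PleC", "PleC", "PleC",
            "DivL", "DivL", "CckA", "CckA", "CpdR", "CpdR")
  free_sp <- c("DivK", "DivKp", "DivJ", "DivJ_DivK", "DivJ_DivKp",
               "PleC_ph", "PleC_kin", "PleC_DivKp", "DivL", "DivL_DivKp",
               "CckA_kin", "CckA_ph", "CpdR_u", "CpdRp")
  bind_tab <- list(ifree = unname(idx[free_sp]),
                   ibound = unname(idx[paste0(free_sp, "_b")]),
                   fam = fams,
                   kon = vapply(fams, function(f) pl[[paste0("k_on_", f)]], 0),
                   koff = vapply(fams, function(f) pl[[paste0("k_off_", f)]], 0))
  list(p = pl, cat = cat, N = N, idx = idx, ix = list2env(as.list(idx)),
       bind_tab = bind_tab,
       D = .species_diffusivity(cat, pl),
       central = central, boost = boost, S = S,
       compartmentalized = compartmentalized, sep = N %/% 2L,
       l0 = l0, t0 = t0)
}

## Discrete Laplacian with reflecting (no-flux) ends; optionally a closed
## interface between compartments sep and sep+1 (Z-ring closure).
.laplacian <- function(C, blocked_interface = NA_integer_) {
  N <- ncol(C)
  li <- c(1L, seq_len(N - 1L))     # left neighbour (reflect at 1)
  ri <- c(seq.int(2L, N), N)       # right neighbour (reflect at N)
  if (!is.na(blocked_interface)) {
    ri[blocked_interface] <- blocked_interface
    li[blocked_interface + 1L] <- blocked_interface + 1L
  }
  (C[, li, drop = FALSE] - C) + (C[, ri, drop = FALSE] - C)
}

## Reaction rates of the full network, species x compartment.
## C may carry tiny negative excursions from the solver; rate laws are
## polynomial so this is harmless.
.reaction_rates <- function(C, ctx) {
  p <- ctx$p; ix <- ctx$ix; N <- ctx$N
  mu <- p$mu; central <- ctx$central; boost <- ctx$boost; S <- ctx$S
  R <- matrix(0, nrow = nrow(C), ncol = N)

  PopZ_m <- C[ix$PopZ_m, ];  PopZ_p <- C[ix$PopZ_p, ]
  PodJL_m <- C[ix$PodJL_m, ]; PodJL_p <- C[ix$PodJL_p, ]
  PodJS_m <- C[ix$PodJS_m, ]; PodJS_p <- C[ix$PodJS_p, ]
  SpmX_m <- C[ix$SpmX_m, ];  SpmX_p <- C[ix$SpmX_p, ]
  PerP <- C[ix$PerP, ]
  CtrAp <- pmax(C[ix$CtrAp, ], 0)

  PodJL_T <- PodJL_m + PodJL_p
  SpmX_T <- SpmX_m + SpmX_p
  PodJ_pol <- PodJL_p + PodJS_p

  ## --- scaffolding proteins: A-SD Turing pairs -----------------------
  dnv <- p$k_dnv_PopZ * (1 + p$alpha_PopZPodJ * PodJL_T) * PopZ_m
  aut <- p$k_aut_PopZ * boost * PopZ_m * PopZ_p^2
  depol <- p$k_depol_PopZ * PopZ_p
  R[ix$PopZ_m, ] <- p$k_s_PopZ * central -
    (p$k_d_PopZ + mu) * PopZ_m + depol - dnv - aut
  R[ix$PopZ_p, ] <- -(p$k_d_PopZ + mu) * PopZ_p - depol + dnv + aut

  syn_PodJL <- central * (p$k_s_PodJ * ((1 - p$eps_meth) * S[["podJ"]] + p$eps_meth) +
    p$k_s_PodJ2 * p$J_i_PodJCtrA^p$n_PodJ /
      (p$J_i_PodJCtrA^p$n_PodJ + CtrAp^p$n_PodJ))
  kloss_PodJL <- p$k_d_PodJ1 + p$k_d_PodJ2 * PerP + mu
  kaut_PodJ <- p$k_aut_PodJ / (1 + p$alpha_PodJSpmX * SpmX_T) * boost
  dnv <- p$k_dnv_PodJ * PodJL_m
  aut <- kaut_PodJ * PodJL_m * PodJL_p^2
  depol <- p$k_depol_PodJ * PodJL_p
  conv_m <- p$k_d_PodJ2 * PerP * PodJL_m
  conv_p <- p$k_d_PodJ2 * PerP * PodJL_p
  R[ix$PodJL_m, ] <- syn_PodJL - kloss_PodJL * PodJL_m + depol - dnv - aut
  R[ix$PodJL_p, ] <- -kloss_PodJL * PodJL_p - depol + dnv + aut

  dnv <- p$k_dnv_PodJS * PodJS_m
  aut <- p$k_aut_PodJS * boost * PodJS_m * PodJS_p^2
  depol <- p$k_depol_PodJS * PodJS_p
  R[ix$PodJS_m, ] <- conv_m - (p$k_d_PodJS + mu) * PodJS_m + depol - dnv - aut
  R[ix$PodJS_p, ] <- conv_p - (p$k_d_PodJS + mu) * PodJS_p - depol + dnv + aut

  ## SpmX nucleates on PopZ polymer; PodJ polymer excludes it from the
  ## new pole (the poles are mutually exclusive scaffold territories)
  dnv <- p$k_dnv_SpmX * (1 + p$alpha_SpmXPopZ * PopZ_p) /
    (1 + p$alpha_SpmXPodJ * PodJ_pol) * SpmX_m
  aut <- p$k_aut_SpmX * SpmX_m * SpmX_p^2
  depol <- p$k_depol_SpmX * SpmX_p
  R[ix$SpmX_m, ] <- p$k_s_SpmX * central -
    (p$k_d_SpmX + mu) * SpmX_m + depol - dnv - aut
  R[ix$SpmX_p, ] <- -(p$k_d_SpmX + mu) * SpmX_p - depol + dnv + aut

  ## --- PerP protease --------------------------------------------------
  R[ix$PerP, ] <- central * p$k_s_PerP *
    ((1 - p$eps_meth) * S[["perP"]] + p$eps_meth) *
    CtrAp^2 / (p$J_a_PerPCtrA^2 + CtrAp^2) -
    (p$k_d_PerP + mu) * PerP

  ## --- polar membrane exchange ----------------------------------------
  DivL_b <- C[ix$DivL_b, ]; DivL_DivKp_b <- C[ix$DivL_DivKp_b, ]
  enh <- list(
    DivK = 1 + p$k_fb_DivK * PopZ_p,
    DivJ = 1 + p$k_fb_DivJ * SpmX_p,
    PleC = 1 + p$k_fb_PleC * PodJ_pol,
    DivL = 1 + p$alpha_DivLPodJ * PodJ_pol + p$k_fb_DivLPopZ * PopZ_p,
    CckA = 1 + p$k_fb_CckA * (DivL_b + DivL_DivKp_b) + p$k_fb_CckAPopZ * PopZ_p,
    CpdR = 1 + p$k_fb_CpdR * PopZ_p)
  bt <- ctx$bind_tab
  for (k in seq_along(bt$ifree)) {
    on <- bt$kon[k] * enh[[bt$fam[k]]] * C[bt$ifree[k], ]
    off <- bt$koff[k] * C[bt$ibound[k], ]
    R[bt$ifree[k], ] <- R[bt$ifree[k], ] - on + off
    R[bt$ibound[k], ] <- R[bt$ibound[k], ] + on - off
  }

  ## --- DivJ/PleC <-> DivK phosphorelay (cyto and membrane layers) -----
  DivK <- C[ix$DivK, ]; DivKp <- C[ix$DivKp, ]
  dDivK <- 0; dDivKp <- 0
  lay <- rbind(cyto = c(ix$DivJ, ix$DivJ_DivK, ix$DivJ_DivKp, ix$PleC_ph,
                        ix$PleC_kin, ix$PleC_DivKp, ix$DivL, ix$DivL_DivKp),
               mem = c(ix$DivJ_b, ix$DivJ_DivK_b, ix$DivJ_DivKp_b,
                       ix$PleC_ph_b, ix$PleC_kin_b, ix$PleC_DivKp_b,
                       ix$DivL_b, ix$DivL_DivKp_b))
  for (layer in 1:2) {
    iJ <- lay[layer, 1]; iJK <- lay[layer, 2]; iJKp <- lay[layer, 3]
    iPh <- lay[layer, 4]; iKin <- lay[layer, 5]; iPKp <- lay[layer, 6]
    iL <- lay[layer, 7]; iLKp <- lay[layer, 8]
    a1 <- p$k_bind_DivJDivK * C[iJ, ] * DivK
    d1 <- p$k_unbind_DivJDivK * C[iJK, ]
    a2 <- p$k_bind_DivJDivKp * C[iJ, ] * DivKp
    d2 <- p$k_unbind_DivJDivKp * C[iJKp, ]
    ## phosphotransfer requires the polar (membrane-bound) complex:
    ## DivJ kinase activity is coupled to its scaffold localization
    ph <- if (layer == 2L) p$k_ph_DivJ * C[iJK, ] else 0
    R[iJ, ] <- R[iJ, ] - a1 + d1 - a2 + d2
    R[iJK, ] <- R[iJK, ] + a1 - d1 - ph
    R[iJKp, ] <- R[iJKp, ] + a2 - d2 + ph
    dDivK <- dDivK - a1 + d1
    dDivKp <- dDivKp - a2 + d2

    ab <- p$k_bind_PleCDivKp * C[iPh, ] * DivKp
    db <- p$k_unbind_PleCDivKp * C[iPKp, ]
    ct <- p$k_cat_PleC * C[iPKp, ]     # dephosphorylate and release DivK
    sw <- p$k_sw_PleC * C[iPKp, ]      # conformational switch to kinase
    rx <- p$k_rx_PleC * C[iKin, ]
    R[iPh, ] <- R[iPh, ] - ab + db + ct + rx
    R[iKin, ] <- R[iKin, ] + sw - rx
    R[iPKp, ] <- R[iPKp, ] + ab - db - ct - sw
    dDivKp <- dDivKp - ab + db + sw
    dDivK <- dDivK + ct

    al <- p$k_bind_DivLDivKp * C[iL, ] * DivKp
    dl <- p$k_unbind_DivLDivKp * C[iLKp, ]
    R[iL, ] <- R[iL, ] - al + dl
    R[iLKp, ] <- R[iLKp, ] + al - dl
    dDivKp <- dDivKp - al + dl
  }
  kin_flux <- p$k_kin_PleC * (C[ix$PleC_kin, ] + C[ix$PleC_kin_b, ]) * DivK
  dDivK <- dDivK - kin_flux
  dDivKp <- dDivKp + kin_flux

  ## --- CckA kinase/phosphatase switch and downstream transfer ---------
  CckA_kin_tot <- C[ix$CckA_kin, ] + C[ix$CckA_kin_b, ]
  CckA_ph_tot <- C[ix$CckA_ph, ] + C[ix$CckA_ph_b, ]
  ## the allosteric switch is layer-matched: membrane CckA responds to
  ## the co-localized membrane DivL:DivK~P complex, cytosolic CckA to
  ## the cytosolic complex
  cck <- rbind(c(ix$CckA_kin, ix$CckA_ph, ix$DivL_DivKp, ix$CpdR_u, ix$CpdRp),
               c(ix$CckA_kin_b, ix$CckA_ph_b, ix$DivL_DivKp_b,
                 ix$CpdR_u_b, ix$CpdRp_b))
  for (layer in 1:2) {
    iK <- cck[layer, 1]; iP <- cck[layer, 2]; iDLK <- cck[layer, 3]
    iRu <- cck[layer, 4]; iRp <- cck[layer, 5]
    kp <- p$k_kp_CckA * C[iDLK, ] * C[iK, ]
    pk <- p$k_pk_CckA * C[iP, ]
    R[iK, ] <- R[iK, ] - kp + pk
    R[iP, ] <- R[iP, ] + kp - pk
    phR <- p$k_ph_CpdR * CckA_kin_tot * C[iRu, ]
    dphR <- p$k_deph_CpdR * CckA_ph_tot * C[iRp, ]
    R[iRu, ] <- R[iRu, ] - phR + dphR
    R[iRp, ] <- R[iRp, ] + phR - dphR
  }
  phC <- p$k_ph_CtrA * CckA_kin_tot * C[ix$CtrA_u, ]
  dphC <- p$k_deph_CtrA * CckA_ph_tot * CtrAp
  R[ix$CtrA_u, ] <- R[ix$CtrA_u, ] - phC + dphC
  R[ix$CtrAp, ] <- R[ix$CtrAp, ] + phC - dphC

  ## --- synthesis, degradation, dilution of signaling proteins ---------
  dDivK <- dDivK + central * p$k_s_DivK - (p$k_d_DivK + mu) * DivK
  dDivKp <- dDivKp - (p$k_d_DivK + mu) * DivKp
  R[ix$DivK, ] <- R[ix$DivK, ] + dDivK
  R[ix$DivKp, ] <- R[ix$DivKp, ] + dDivKp
  R[ix$DivK_b, ] <- R[ix$DivK_b, ] - (p$k_d_DivK + mu) * C[ix$DivK_b, ]
  R[ix$DivKp_b, ] <- R[ix$DivKp_b, ] - (p$k_d_DivK + mu) * C[ix$DivKp_b, ]
  R[ix$DivJ, ] <- R[ix$DivJ, ] + central * p$k_s_DivJ
  R[ix$PleC_ph, ] <- R[ix$PleC_ph, ] + central * p$k_s_PleC *
    ((1 - p$eps_meth) * S[["pleC"]] + p$eps_meth)
  R[ix$DivL, ] <- R[ix$DivL, ] + central * p$k_s_DivL
  R[ix$CckA_kin, ] <- R[ix$CckA_kin, ] + central * p$k_s_CckA
  R[ix$CpdR_u, ] <- R[ix$CpdR_u, ] + central * p$k_s_CpdR
  R[ix$CtrA_u, ] <- R[ix$CtrA_u, ] +
    central * ((1 - p$eps_meth) * S[["ctrA"]] + p$eps_meth) *
    (p$k_s_CtrA1 * p$J_i_CtrAP^p$n_CtrA / (p$J_i_CtrAP^p$n_CtrA + CtrAp^p$n_CtrA) +
     p$k_s_CtrA2 * CtrAp^p$n_CtrA / (p$J_a_CtrAP^p$n_CtrA + CtrAp^p$n_CtrA))

  kdtab <- rbind(c(ix$DivJ, ix$DivJ_b), c(ix$PleC_ph, ix$PleC_ph_b),
                 c(ix$PleC_kin, ix$PleC_kin_b), c(ix$DivL, ix$DivL_b),
                 c(ix$CckA_kin, ix$CckA_kin_b), c(ix$CckA_ph, ix$CckA_ph_b),
                 c(ix$CpdR_u, ix$CpdR_u_b), c(ix$CpdRp, ix$CpdRp_b))
  kdval <- c(p$k_d_DivJ, p$k_d_PleC, p$k_d_PleC, p$k_d_DivL,
             p$k_d_CckA, p$k_d_CckA, p$k_d_CpdR, p$k_d_CpdR)
  for (k in seq_along(kdval)) {
    R[kdtab[k, 1], ] <- R[kdtab[k, 1], ] - (kdval[k] + mu) * C[kdtab[k, 1], ]
    R[kdtab[k, 2], ] <- R[kdtab[k, 2], ] - (kdval[k] + mu) * C[kdtab[k, 2], ]
  }
  ## complexes: dilution only (degradation acts on the free pools)
  for (i in c(ix$DivJ_DivK, ix$DivJ_DivK_b, ix$DivJ_DivKp, ix$DivJ_DivKp_b,
              ix$PleC_DivKp, ix$PleC_DivKp_b, ix$DivL_DivKp, ix$DivL_DivKp_b))
    R[i, ] <- R[i, ] - mu * C[i, ]
  ## CtrA: basal + CpdR(u)-dependent proteolysis of both forms
  kdeg <- p$k_d_CtrA + p$k_deg_CtrA * (C[ix$CpdR_u, ] + C[ix$CpdR_u_b, ]) + mu
  R[ix$CtrA_u, ] <- R[ix$CtrA_u, ] - kdeg * C[ix$CtrA_u, ]
  R[ix$CtrAp, ] <- R[ix$CtrAp, ] - kdeg * CtrAp
  R
}

## deSolve-facing right-hand side: reactions + no-flux diffusion on the
## exponentially growing grid.
.rhs_core <- function(t, y, ctx) {
  C <- matrix(y, nrow = length(ctx$idx))
  l <- ctx$l0 * exp(ctx$p$mu * (t - ctx$t0))
  lap <- .laplacian(C, if (ctx$compartmentalized) ctx$sep else NA_integer_)
  dC <- .reaction_rates(C, ctx) + (ctx$D / l^2) * lap
  list(as.vector(dC))
}

#' Assemble the full right-hand side of the model
#'
#' Evaluates the time-derivative of every species in every compartment:
#' synthesis (central compartments only, gated by promoter methylation
#' and CtrA~P Hill regulation), degradation and dilution, polymer and
#' complex exchange, the phosphotransfer fluxes of the two relay
#' modules, polar membrane binding, and no-flux diffusion.
#'
#' @param state a [spatial_state()].
#' @param p parameter table.
#' @param ev cycle event state ([cycle_event_state()]), supplying the
#'   methylation flags and the compartmentalization switch.
#' @param cat species catalog; defaults to the full 39-species model.
#' @return a species-by-compartment matrix of time derivatives (conc/min).
#' @export
assemble_rhs <- function(state, p, ev = cycle_event_state(),
                         cat = species_catalog()) {
  if (nrow(state$conc) != nrow(cat))
    stop("state has ", nrow(state$conc), " species but catalog has ", nrow(cat))
  if (!all(rownames(state$conc) == cat$name))
    stop("state species do not match the catalog")
  ctx <- .make_context(p, cat, state$N, S = ev$S,
                       compartmentalized = ev$compartmentalized,
                       l0 = state$l, t0 = state$t)
  d <- .rhs_core(state$t, as.vector(state$conc), ctx)[[1]]
  m <- matrix(d, nrow = nrow(cat), dimnames = list(cat$name, NULL))
  m
}
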