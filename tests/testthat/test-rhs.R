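test_that("the assembled right-hand side vanishes on an empty cell", {
  p <- zeroed_params()
  cat39 <- species_catalog()
  conc <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  d <- assemble_rhs(spatial_state(conc, l = 0.2), p)
  expect_true(all(d == 0))
})

test_that("a spatially uniform state receives no diffusion flux", {
  p <- default_parameters()
  cat39 <- species_catalog()
  conc <- matrix(0.7, 39, 10, dimnames = list(cat39$name, NULL))
  s <- spatial_state(conc, l = 0.2)
  d_full <- assemble_rhs(s, p)
  ## zero out every diffusivity: the derivative must not change except
  ## for the polar/central reaction heterogeneity, which is identical
  pz <- set_params(p, c(alpha_D = 0, D0 = 0, D_PopZ_p = 0, D_PodJL_p = 0,
                        D_PodJS_p = 0, D_SpmX_p = 0, D_b_DivK = 0,
                        D_b_DivJ = 0, D_b_PleC = 0, D_b_DivL = 0,
                        D_b_CckA = 0, D_b_CpdR = 0))
  pz$value[pz$name == "D0"] <- 0
  d_nodiff <- assemble_rhs(s, pz)
  expect_equal(d_full, d_nodiff, tolerance = 1e-12)
})

test_that("single-species decay gives -(k_d + mu) C in every compartment", {
  p <- zeroed_params(keep = c(k_d_PerP = 0.2, mu = 0.01))
  cat39 <- species_catalog()
  conc <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  conc["PerP", ] <- seq(0.1, 1, length.out = 10)
  d <- assemble_rhs(spatial_state(conc, l = 0.2), p)
  ## reaction part plus diffusion of the non-uniform profile
  diff_part <- diffusion_term(conc["PerP", ],
                              60 * diffusion_coefficient(24), 0.2)
  expect_equal(d["PerP", ], -(0.2 + 0.01) * conc["PerP", ] + diff_part,
               tolerance = 1e-10)
  expect_true(all(d[rownames(d) != "PerP", ] == 0))
})

test_that("phospho and binding fluxes conserve each protein family", {
  set.seed(21)
  p <- zeroed_params(keep = c(
    k_ph_DivJ = 3, k_bind_DivJDivK = 4, k_unbind_DivJDivK = 0.5,
    k_bind_DivJDivKp = 2, k_unbind_DivJDivKp = 0.5,
    k_bind_PleCDivKp = 4, k_unbind_PleCDivKp = 0.5, k_cat_PleC = 20,
    k_sw_PleC = 0.3, k_rx_PleC = 1, k_kin_PleC = 0.3,
    k_bind_DivLDivKp = 1, k_unbind_DivLDivKp = 1,
    k_kp_CckA = 10, k_pk_CckA = 0.6, k_ph_CtrA = 3, k_deph_CtrA = 6,
    k_ph_CpdR = 6, k_deph_CpdR = 6,
    k_on_DivK = 0.02, k_off_DivK = 0.2, k_on_DivJ = 0.05, k_off_DivJ = 0.3,
    k_on_PleC = 0.02, k_off_PleC = 0.3, k_on_DivL = 0.02, k_off_DivL = 0.3,
    k_on_CckA = 0.02, k_off_CckA = 0.3, k_on_CpdR = 0.02, k_off_CpdR = 0.3,
    k_fb_DivK = 5, k_fb_DivJ = 100, k_fb_PleC = 20, alpha_DivLPodJ = 15,
    k_fb_DivLPopZ = 3, k_fb_CckA = 20, k_fb_CckAPopZ = 2, k_fb_CpdR = 10))
  cat39 <- species_catalog()
  tm <- caulopolar:::.totals_map
  for (rep in 1:10) {
    conc <- matrix(runif(39 * 10, 0, 2), 39, 10,
                   dimnames = list(cat39$name, NULL))
    d <- assemble_rhs(spatial_state(conc, l = 0.2), p)
    for (fam in c("DivK", "DivJ", "PleC", "DivL", "CckA", "CpdR", "CtrA"))
      expect_equal(sum(d[tm[[fam]], ]), 0, tolerance = 1e-10)
  }
})

test_that("rhs is finite for any nonnegative state below 1e6", {
  p <- default_parameters()
  cat39 <- species_catalog()
  set.seed(5)
  for (scale in c(1, 1e3, 1e6)) {
    conc <- matrix(runif(39 * 10, 0, scale), 39, 10,
                   dimnames = list(cat39$name, NULL))
    d <- assemble_rhs(spatial_state(conc, l = 0.2), p)
    expect_true(all(is.finite(d)))
  }
})

test_that("dimension mismatches are rejected", {
  p <- default_parameters()
  conc <- matrix(0, 10, 10)
  expect_error(assemble_rhs(spatial_state(conc, l = 0.2), p), "species")
})
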