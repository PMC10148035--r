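test_that("species catalog has the full model's structure", {
  cat39 <- species_catalog()
  expect_s3_class(cat39, "caulo_catalog")
  expect_identical(nrow(cat39), 39L)
  expect_true(validate_catalog(cat39))
  expect_false(anyDuplicated(cat39$name) > 0)
  mono <- cat39[cat39$form == "monomer", ]
  expect_true(all(mono$mw > 0))
  cx <- cat39[cat39$form == "complex", ]
  expect_true(all(lengths(strsplit(cx$partners, ";")) >= 2))
  ## the DivK complexes of the signaling network are all present
  expect_true(all(c("PleC_DivKp", "DivL_DivKp", "DivJ_DivKp", "DivJ_DivK")
                  %in% cat39$name))
})

test_that("parameter table has 110 constants with 41 estimated", {
  p <- default_parameters()
  expect_identical(nrow(p), 110L)
  expect_identical(sum(p$group == "estimated"), 41L)
  expect_identical(sum(p$group == "fixed"), 69L)
  expect_true(all(p$value >= 0))
  expect_true(all(p$value >= p$lower & p$value <= p$upper))
  expect_true(validate_parameters(p))
  ## estimated bounds are the 0.4x / 1.5x reseeding window
  est <- p[p$group == "estimated", ]
  expect_equal(est$lower, 0.4 * est$value)
  expect_equal(est$upper, 1.5 * est$value)
  ## named constants of the printed equations are present
  expect_true(all(c("k_s_PopZ", "k_d_PopZ", "k_depol_PopZ", "k_dnv_PopZ",
                    "k_aut_PopZ", "alpha_PopZPodJ", "k_s_PodJ", "k_s_PodJ2",
                    "k_d_PodJ1", "k_d_PodJ2", "alpha_PodJSpmX",
                    "J_i_PodJCtrA", "eps_meth", "theta", "mu", "k_fb_PleC",
                    "alpha_DivLPodJ") %in% p$name))
})

test_that("set_params is pure and rejects unknown names", {
  p <- default_parameters()
  p2 <- set_params(p, c(k_s_PopZ = 99))
  expect_equal(param_value(p2, "k_s_PopZ"), 99)
  expect_equal(param_value(p, "k_s_PopZ"), 0.03)  # input untouched
  expect_error(set_params(p, c(nonexistent = 1)), "unknown parameter")
  expect_error(param_value(p, "nope"), "unknown parameter")
})

test_that("parameter and catalog tables round-trip losslessly through CSV", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(p, f)
  p2 <- read_parameter_table(f)
  expect_equal(p2$value, p$value)
  expect_identical(p2$name, p$name)
  expect_identical(p2$group, p$group)
  ## and a second pass is identical to the first (idempotent)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(p2, f2)
  expect_identical(readLines(f), readLines(f2))

  cf <- withr::local_tempfile(fileext = ".csv")
  write_species_catalog(species_catalog(), cf)
  c2 <- read_species_catalog(cf)
  expect_identical(c2$name, species_catalog()$name)
  expect_equal(c2$mw, species_catalog()$mw)
})

test_that("packaged extdata files load and validate", {
  pf <- system.file("extdata", "parameters.csv", package = "caulopolar")
  expect_true(nzchar(pf))
  expect_true(validate_parameters(read_parameter_table(pf)))
  gf <- system.file("extdata", "gene_coordinates.csv", package = "caulopolar")
  g <- read_gene_coordinates(gf)
  expect_setequal(g$gene, c("ctrA", "pleC", "perP", "podJ"))
  sf <- system.file("extdata", "strain_catalog.json", package = "caulopolar")
  sc <- read_strain_catalog(sf)
  expect_true(all(c("WT", "dpodJ", "dpleC", "pleC_H610A") %in% names(sc)))
})
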