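test_that("Hill activation and inhibition take their textbook values", {
  expect_equal(hill_activation(1, 1, 2), 0.5)
  expect_equal(hill_activation(0, 3, 4), 0)
  expect_equal(hill_activation(2, 1, 4), 16 / 17)
  expect_equal(hill_inhibition(1, 1, 2), 0.5)
  expect_equal(hill_inhibition(0, 3, 4), 1)
  expect_equal(hill_inhibition(2, 1, 4), 1 / 17)
  expect_error(hill_activation(-1, 1, 2), "nonnegative")
  expect_error(hill_activation(1, 0, 2), "positive")
})

test_that("activation and inhibition are exact complements for any x", {
  x <- c(0, 10^seq(-6, 5, length.out = 40))
  for (n in c(1, 2, 4)) {
    s <- hill_activation(x, J = 0.37, n = n) + hill_inhibition(x, J = 0.37, n = n)
    expect_equal(s, rep(1, length(x)), tolerance = 1e-14)
  }
})

test_that("methylation factor interpolates between leak and full rate", {
  expect_equal(methylation_factor(1, 0.05), 1)
  expect_equal(methylation_factor(0, 0.05), 0.05)
  expect_equal(methylation_factor(0, 1), 1)
  expect_equal(methylation_factor(1, 1), 1)
  expect_error(methylation_factor(0.5, 0.05), "0 or 1")
  expect_error(methylation_factor(1, 0), "\\(0, 1\\]")
})

test_that("mass-law diffusivity matches its closed form and decreases in mass", {
  expect_equal(diffusion_coefficient(100), 1.08)
  expect_equal(diffusion_coefficient(10), 43.65)
  expect_lt(abs(diffusion_coefficient(1e6) - 0.65), 1e-5)
  mw <- seq(10, 200, by = 5)
  expect_true(all(diff(diffusion_coefficient(mw)) < 0))
  expect_error(diffusion_coefficient(0), "positive")
})

test_that("PopZ reaction kernel reproduces worked examples", {
  p0 <- zeroed_params(keep = c(k_aut_PopZ = 0.1))
  r <- popz_rates(1, 2, 0, p0, polar = FALSE)
  expect_equal(r$rate_m, -0.4)
  expect_equal(r$rate_p, 0.4)
  r <- popz_rates(1, 2, 0, p0, polar = TRUE)
  expect_equal(r$rate_m, -0.5)
  expect_equal(r$rate_p, 0.5)
  r <- popz_rates(0, 0, 5, default_parameters())
  expect_equal(r$rate_m, 0)
  expect_equal(r$rate_p, 0)
  expect_error(popz_rates(-1, 0, 0, p0), "nonnegative")
})

test_that("PodJL reaction kernel reproduces worked examples", {
  p0 <- zeroed_params(keep = c(k_s_PodJ = 1, k_s_PodJ2 = 1))
  r <- podjl_rates(0, 0, 0, 0, 0, S_podJ = 1, p0, polar = FALSE)
  expect_equal(r$rate_m, 2)
  expect_equal(r$rate_p, 0)
  ## SpmX suppression of autocatalysis
  p0 <- zeroed_params(keep = c(k_aut_PodJ = 0.2, alpha_PodJSpmX = 1))
  r <- podjl_rates(1, 1, 1, 0, 0, S_podJ = 1, p0)
  expect_equal(r$rate_m, -0.1)
  expect_equal(r$rate_p, 0.1)
  ## PerP truncation is a conversion into the short-form pool
  p0 <- zeroed_params(keep = c(k_d_PodJ2 = 0.5))
  r <- podjl_rates(1, 0, 0, 0, 2, S_podJ = 1, p0)
  expect_equal(r$rate_m, -1)
  expect_equal(r$rate_p, 0)
  expect_equal(r$podjs_m_src, 1)
  expect_equal(r$podjs_p_src, 0)
  ## polar compartments synthesize nothing
  p0 <- zeroed_params(keep = c(k_s_PodJ = 1, k_s_PodJ2 = 1))
  r <- podjl_rates(0, 0, 0, 0, 0, S_podJ = 1, p0, polar = TRUE)
  expect_equal(r$rate_m, 0)
})

test_that("polymer exchange terms conserve scaffold protein algebraically", {
  set.seed(11)
  p0 <- default_parameters()
  ## with degradation, dilution and synthesis removed, monomer + polymer
  ## rates must cancel exactly: only exchange terms remain
  pz <- set_params(p0, c(k_d_PopZ = 0, k_d_PodJ1 = 0, k_d_PodJ2 = 0, mu = 0,
                         k_s_PodJ = 0, k_s_PodJ2 = 0))
  for (i in 1:25) {
    m <- runif(1, 0, 5); pp <- runif(1, 0, 5); tot <- runif(1, 0, 3)
    r <- popz_rates(m, pp, tot, pz, polar = sample(c(TRUE, FALSE), 1))
    expect_equal(r$rate_m + r$rate_p, 0, tolerance = 1e-12)
    r <- podjl_rates(m, pp, tot, runif(1, 0, 2), 0, S_podJ = 1, pz,
                     polar = sample(c(TRUE, FALSE), 1))
    expect_equal(r$rate_m + r$rate_p, 0, tolerance = 1e-12)
  }
})

test_that("rate kernels stay finite over a wide concentration range", {
  p <- default_parameters()
  big <- c(0, 1, 1e3, 1e6)
  for (m in big) for (pp in big) {
    expect_true(all(is.finite(unlist(popz_rates(m, pp, 1e6, p)))))
    expect_true(all(is.finite(unlist(
      podjl_rates(m, pp, 1e6, 1e6, 1e6, 1, p)))))
  }
})
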