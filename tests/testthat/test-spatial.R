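test_that("diffusion operator applies the no-flux second difference", {
  expect_equal(diffusion_term(c(0, 1, 0), D = 1, l = 1), c(1, -2, 1))
  expect_equal(diffusion_term(rep(3.7, 8), D = 2, l = 0.3), rep(0, 8))
  ## halving the compartment length quadruples the rates
  c0 <- c(1, 4, 2, 0.5)
  expect_equal(diffusion_term(c0, 1, 0.5), 4 * diffusion_term(c0, 1, 1))
  expect_error(diffusion_term(1, 1, 1), "at least 2")
  expect_error(diffusion_term(c(1, 2), 1, 0), "positive")
})

test_that("diffusion conserves total amount for arbitrary profiles", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(2:40, 1)
    out <- diffusion_term(runif(N, 0, 10), D = runif(1, 0, 5),
                          l = runif(1, 0.1, 1))
    expect_equal(sum(out), 0, tolerance = 1e-10)
  }
})

test_that("exponential growth reproduces the division-length calibration", {
  expect_equal(grow_step(5, 0, 100), 5)
  mu <- log(4.4 / 2) / 150
  expect_equal(grow_step(2, mu, 150), 4.4, tolerance = 1e-12)
  expect_equal(round(mu, 4), 0.0053)
  expect_error(grow_step(-1, 0.1, 1), "positive")
})

test_that("a pure-decay species follows its closed form to 1e-6 relative", {
  p <- zeroed_params(keep = c(k_d_PerP = 0.1))
  cat39 <- species_catalog()
  conc <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  conc["PerP", ] <- 2.5
  s0 <- spatial_state(conc, l = 0.2)
  tr <- integrate_interval(s0, p, t_end = 50)
  expected <- 2.5 * exp(-0.1 * tr$times)
  for (i in c(1, 5, 10)) {
    got <- tr$conc["PerP", i, ]
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("with all sources and sinks off, every total is conserved", {
  set.seed(7)
  p <- zeroed_params()
  cat39 <- species_catalog()
  conc <- matrix(runif(39 * 10, 0, 2), 39, 10,
                 dimnames = list(cat39$name, NULL))
  s0 <- spatial_state(conc, l = 0.2)
  tr <- integrate_interval(s0, p, t_end = 30)
  nt <- length(tr$times)
  for (fam in c("PopZ", "PodJ", "SpmX", "DivK", "DivJ", "PleC", "DivL",
                "CckA", "CpdR", "CtrA")) {
    tot <- species_total(tr, fam)
    expect_equal(tot[nt] / tot[1], 1, tolerance = 1e-8)
  }
})

test_that("division conserves amounts and re-grids piecewise-constantly", {
  set.seed(9)
  cat39 <- species_catalog()
  conc <- matrix(runif(39 * 10, 0, 3), 39, 10,
                 dimnames = list(cat39$name, NULL))
  mother <- spatial_state(conc, l = 0.4, t = 140)
  d <- divide(mother)
  ## exact conservation of every species
  mother_tot <- rowSums(conc) * mother$l
  kids_tot <- rowSums(d$swarmer$conc) * d$swarmer$l +
    rowSums(d$stalked$conc) * d$stalked$l
  expect_equal(kids_tot, mother_tot)
  expect_equal(d$swarmer$l, 0.2)
  expect_identical(d$swarmer$N, 10L)
  ## uniform mother -> two uniform daughters at the same concentration
  u <- spatial_state(matrix(2, 39, 10, dimnames = list(cat39$name, NULL)),
                     l = 0.4)
  du <- divide(u)
  expect_true(all(du$swarmer$conc == 2) && all(du$stalked$conc == 2))
  ## step profile: 1 in the new-pole half -> swarmer uniform 1, stalked 0
  st <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  st[, 1:5] <- 1
  ds <- divide(spatial_state(st, l = 0.4))
  expect_true(all(ds$swarmer$conc == 1))
  expect_true(all(ds$stalked$conc == 0))
  ## orientation: mother's new pole becomes the swarmer's old pole
  orient <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  orient["PerP", 1] <- 7
  dor <- divide(spatial_state(orient, l = 0.4))
  expect_equal(dor$swarmer$conc["PerP", 9:10], c(7, 7))
  expect_error(divide(spatial_state(st[, 1:9], l = 0.4)), "even")
})

test_that("compartmentalization blocks diffusion across the midcell", {
  cat39 <- species_catalog()
  conc <- matrix(0, 39, 10, dimnames = list(cat39$name, NULL))
  conc["PerP", 1:5] <- 1     # step profile against the closed interface
  s0 <- spatial_state(conc, l = 0.2)
  ev <- cycle_event_state()
  ev$compartmentalized <- TRUE
  p <- zeroed_params()
  tr <- integrate_interval(s0, p, ev, t_end = 30)
  nt <- length(tr$times)
  half1 <- sum(tr$conc["PerP", 1:5, nt])
  half2 <- sum(tr$conc["PerP", 6:10, nt])
  expect_equal(half1, 5, tolerance = 1e-7)
  expect_equal(half2, 0, tolerance = 1e-7)
})
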