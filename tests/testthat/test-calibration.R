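test_that("series normalization divides by the maximum and is idempotent", {
  expect_equal(normalize_series(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalize_series(rep(3, 5)), rep(1, 5))
  y <- c(0.2, 0.7, 1)
  expect_equal(normalize_series(y), y)
  expect_error(normalize_series(c(0, 0)), "positive")
})

test_that("fit_scale is the least-squares scale factor", {
  x <- c(1, 3, 2, 5)
  expect_equal(fit_scale(x, x), 1)
  expect_equal(fit_scale(x, 2 * x), 0.5)
  expect_equal(fit_scale(c(1, 0), c(0, 1)), 0)  # orthogonal vectors
  expect_error(fit_scale(x, rep(0, 4)), "degenerate")
  ## it minimizes the quadratic: perturbing never improves
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    s <- fit_scale(x, y)
    obj <- function(sc) sum((x - sc * y)^2)
    for (d in c(-0.1, -1e-3, 1e-3, 0.1))
      expect_gte(obj(s + d), obj(s))
  }
})

test_that("the temporal objective is zero on a perfect fit and adds the timing penalty", {
  ## constant totals: CtrA_u = 1 everywhere -> whole-cell total 2
  tr <- synthetic_trajectory(list(CtrA_u = 1))
  trajs <- list(cycle2 = tr, cycle3 = tr)
  data <- list(experimental_series("CtrA", times = c(0, 4, 8),
                                   values = rep(1, 3), weight = 400))
  expect_equal(objective_f1(trajs, data, T_ini = 25), 0)
  expect_equal(objective_f1(trajs, data, T_ini = 28), 0)  # inside the band
  expect_equal(objective_f1(trajs, data, T_ini = 35), 25) # (10 - 5)^2
  expect_equal(objective_f1(trajs, data, T_ini = 15), 25)
  ## a mismatch contributes (weight / n) * sum(((x - y)/max(y))^2)
  bad <- list(experimental_series("CtrA", times = c(0, 4, 8),
                                  values = c(1, 0.5, 1), weight = 400))
  f <- objective_f1(trajs, bad, T_ini = 25)
  expect_gt(f, 0)
  expect_error(objective_f1(list(cycle2 = tr), data, 25), "missing")
})

test_that("spatial penalties reproduce the worked all-central value", {
  ## PopZ absent from the poles, uniform c in the 8 central compartments
  prof <- rep(1, 10); prof[c(1, 10)] <- 0
  tr <- synthetic_trajectory(list(PopZ_p = prof))
  expect_equal(spatial_penalty_popz(tr), 28.515625)
  ## exactly at the required ratios the penalty vanishes
  ok <- rep(1, 10); ok[1] <- 4; ok[10] <- 1.5
  expect_equal(spatial_penalty_popz(synthetic_trajectory(list(PopZ_p = ok))), 0)
  ## DivK~P: meeting or exceeding 2x central is free, shortfall is not
  dk <- rep(1, 10); dk[1] <- 3
  expect_equal(spatial_penalty_divk(synthetic_trajectory(list(DivKp = dk))), 0)
  dk[1] <- 1
  expect_gt(spatial_penalty_divk(synthetic_trajectory(list(DivKp = dk))), 0)
  ## f2 combines both with weights 100 and 1 over two cycles
  tr2 <- synthetic_trajectory(list(PopZ_p = ok, DivKp = rep(1, 10)))
  f2 <- objective_f2(list(cycle2 = tr2, cycle3 = tr2))
  expect_equal(f2, 2 * 1 * (min(0, (1 - 2) / 1))^2)
})

test_that("nondominated sorting matches a brute-force dominance check", {
  set.seed(31)
  F <- matrix(runif(60), ncol = 2)
  rank <- caulopolar:::.nds_rank(F)
  dominated <- vapply(seq_len(nrow(F)), function(i)
    any(vapply(seq_len(nrow(F)), function(j)
      i != j && all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]), TRUE)), TRUE)
  expect_identical(rank == 1L, !dominated)
})

test_that("the evolutionary search respects bounds, purity and determinism", {
  p <- default_parameters()
  target <- p$value[p$group == "estimated"] * 1.2
  ## cheap analytic two-objective surrogate keeps this test fast
  surrogate <- function(pt, dat) {
    x <- pt$value[pt$group == "estimated"]
    c(sum(((x - target) / target)^2), sum((x / target)^2))
  }
  fit1 <- estimate_parameters(p, list(), generations = 4, population = 10,
                              rng_seed = 99, evaluator = surrogate)
  fit2 <- estimate_parameters(p, list(), generations = 4, population = 10,
                              rng_seed = 99, evaluator = surrogate)
  expect_identical(fit1$pareto, fit2$pareto)   # bit-for-bit reproducible
  est <- p$value[p$group == "estimated"]
  X <- as.matrix(fit1$pareto[, seq_along(est)])
  expect_true(all(t(X) >= 0.4 * est - 1e-12))
  expect_true(all(t(X) <= 1.5 * est + 1e-12))
  ## the returned set is mutually nondominated (brute force)
  F <- as.matrix(fit1$pareto[, c("f1", "f2")])
  for (i in seq_len(nrow(F))) for (j in seq_len(nrow(F)))
    if (i != j) expect_false(all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]))
  ## progress: the best f1 does not get worse over generations (elitism)
  expect_true(all(diff(fit1$history) <= 1e-12))
  expect_error(estimate_parameters(p[p$group == "fixed", ], list()),
               "no estimated")
})
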