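test_that("kymographs are max-scaled and additive over PodJ forms", {
  set.seed(17)
  nL <- matrix(runif(100, 0, 2), 10)
  nS <- matrix(runif(100, 0, 1), 10)
  tr <- synthetic_trajectory(list(), times = 0:9)
  tr$conc["PodJL_p", , ] <- nL
  tr$conc["PodJS_p", , ] <- nS
  kL <- export_kymograph(tr, "PodJL")
  kT <- export_kymograph(tr, "PodJ")
  expect_equal(max(kL$values), 1)
  expect_equal(max(kT$values), 1)
  ## total PodJ = elementwise sum of the forms before scaling
  expect_equal(kT$values * max(nL + nS), nL + nS, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## constant-in-time state gives identical columns
  tru <- synthetic_trajectory(list(PopZ_p = seq(0.1, 1, length.out = 10)))
  ku <- export_kymograph(tru, "PopZ")
  expect_true(all(apply(ku$values, 1, function(r) diff(range(r)) == 0)))
  ## y-axis runs from the new pole (+1, compartment 1) to the old (-1)
  expect_gt(ku$y[1], 0)
  expect_lt(ku$y[10], 0)
  expect_error(export_kymograph(tr, "NotASpecies"), "unknown")
})

test_that("focus onset detection finds a persistent polar step", {
  ## polar value jumps from 0 to 10x the central mean at t = 40
  times <- 0:100
  tr <- synthetic_trajectory(list(), times = times)
  tr$conc["PopZ_p", , ] <- 1
  tr$conc["PopZ_p", 1, times >= 40] <- 10
  k <- export_kymograph(tr, "PopZ_p")
  expect_equal(detect_focus_onset(k, "new"), 40)
  expect_true(is.na(detect_focus_onset(k, "old")))
  ## invariant to global rescaling
  k2 <- k
  k2$values <- k$values * 3.7
  expect_equal(detect_focus_onset(k2, "new"), 40)
  ## a uniformly distributed species never has a focus
  tru <- synthetic_trajectory(list(PerP = rep(1, 10)), times = times)
  expect_true(is.na(detect_focus_onset(export_kymograph(tru, "PerP"), "new")))
  ## a blip shorter than the persistence window is ignored
  tb <- synthetic_trajectory(list(), times = times)
  tb$conc["PopZ_p", , ] <- 1
  tb$conc["PopZ_p", 1, 50:52] <- 10
  expect_true(is.na(detect_focus_onset(export_kymograph(tb, "PopZ_p"), "new")))
})

test_that("trajectory exports round-trip deterministically", {
  tr <- synthetic_trajectory(list(PerP = seq(0.1, 1, length.out = 10),
                                  CtrAp = rep(0.5, 10)), times = 0:3)
  df <- trajectory_to_df(tr, c("PerP", "CtrAp"))
  expect_identical(nrow(df), 2L * 10L * 4L)
  expect_equal(df$concentration[df$species == "CtrAp"][1], 0.5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  write_trajectory_csv(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## kymograph CSV has one row per compartment
  kf <- withr::local_tempfile(fileext = ".csv")
  write_kymograph_csv(export_kymograph(tr, "PerP"), kf)
  expect_identical(nrow(utils::read.csv(kf)), 10L)
})

test_that("strain catalogs survive a JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  write_strain_catalog(strain_catalog(), f)
  back <- read_strain_catalog(f)
  expect_setequal(names(back), names(strain_catalog()))
  expect_equal(back$dspmX$set, strain_catalog()$dspmX$set)
  expect_equal(back$PodJ_op2$scale, strain_catalog()$PodJ_op2$scale)
  expect_false(back$dspmX_filament$zring_enabled)
  expect_equal(back$dspmX_filament$sim_duration_override, 750)
})
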