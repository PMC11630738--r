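test_that("fractionator estimate inverts the sampling fractions", {
  # sum Q = 100, interval 4, asf 0.5, tsf 2/3 -> 100*4*2*1.5 = 1200
  d <- fractionator_design(section_interval = 4, frame_x = 10, frame_y = 10,
                           grid_x = 10, grid_y = 20, counting_depth = 20,
                           section_thickness = 30, guard_zone = 1)
  expect_equal(d$asf, 0.5)
  expect_equal(d$tsf, 2 / 3, tolerance = 1e-12)
  expect_equal(fractionator_estimate(c(40, 60), d), 1200)
  # all fractions 1 -> N_hat = sum Q
  d1 <- fractionator_design(section_interval = 1, frame_x = 10, frame_y = 10,
                            grid_x = 10, grid_y = 10, counting_depth = 30,
                            section_thickness = 30, guard_zone = 0)
  expect_equal(fractionator_estimate(c(7, 3), d1), 10)
  # linearity in the counts
  expect_equal(fractionator_estimate(3 * c(40, 60), d),
               3 * fractionator_estimate(c(40, 60), d))
})

test_that("design invariants are enforced with the overlap warning", {
  expect_error(fractionator_design(counting_depth = 29, guard_zone = 1),
               "guard")
  expect_warning(fractionator_design(), "asf > 1")
})

test_that("exhaustive sampling returns the true count exactly", {
  tp <- synth_tissue_params(true_N = c(NeuN = 500),
                            region_extent = c(300, 300, 120), seed = 1)
  d <- fractionator_design(section_interval = 1, frame_x = 300, frame_y = 300,
                           grid_x = 300, grid_y = 300, counting_depth = 30,
                           section_thickness = 30, guard_zone = 0)
  g <- gen_tissue_and_sample(tp, d)
  expect_equal(sum(g$counts$Qminus_NeuN), 500)
  expect_equal(unname(fractionator_estimate(g$counts, d)), 500)
  # true_N = 0 gives all-zero counts
  tp0 <- synth_tissue_params(true_N = c(NeuN = 0),
                             region_extent = c(300, 300, 120), seed = 2)
  g0 <- gen_tissue_and_sample(tp0, d)
  expect_true(all(g0$counts$Qminus_NeuN == 0))
})

test_that("Gundersen CE matches the hand-evaluated m = 1 example", {
  expect_equal(gundersen_ce(rep(10, 5)), sqrt(50 + 50 / 240) / 50,
               tolerance = 1e-12)
  expect_equal(round(gundersen_ce(rep(10, 5)), 4), 0.1417)
  expect_error(gundersen_ce(c(1000)), "3 sections")
  expect_error(gundersen_ce(rep(0, 5)), "zero")
  # proportional scaling: the noise term shrinks CE roughly as 1/sqrt(k)
  ce1 <- gundersen_ce(rep(10, 5))
  ce10 <- gundersen_ce(rep(100, 5))
  expect_lt(ce10, ce1)
  expect_equal(ce10 / ce1, 1 / sqrt(10), tolerance = 0.1)
  # m = 0 variant uses the rougher divisor
  expect_gt(gundersen_ce(c(5, 20, 10, 25, 8), m = 0L),
            gundersen_ce(c(5, 20, 10, 25, 8), m = 1L))
})

test_that("nucleator area is exact on circles and follows the formula", {
  expect_equal(nucleator_area(c(5, 5, 5, 5)), 25 * pi)
  expect_equal(nucleator_area(c(3, 4, 3, 4)), 12.5 * pi)
  expect_error(nucleator_area(c(3, -1, 3, 4)), "non-negative")
})

test_that("nucleator is unbiased over isotropic rays on random profiles", {
  r <- gen_nucleator_rays(10000, seed = 5)
  est <- pi * rowMeans(as.matrix(r[, c("l1", "l2", "l3", "l4")])^2)
  expect_equal(mean(est / r$true_area), 1, tolerance = 0.01)
})

test_that("counting rules exclude edges and guard zones", {
  frame <- list(x0 = 0, y0 = 0, w = 100, h = 100)
  # top exactly on the left exclusion edge: not counted
  expect_equal(apply_counting_rules(
    data.frame(x = 0, y = 50, z = 10), frame, guard = 1, depth = 20), 0)
  # top on the right inclusion edge: counted
  expect_equal(apply_counting_rules(
    data.frame(x = 100, y = 50, z = 10), frame, guard = 1, depth = 20), 1)
  # top in the guard zone: not counted
  expect_equal(apply_counting_rules(
    data.frame(x = 50, y = 50, z = 0.5), frame, guard = 1, depth = 20), 0)
  # exhaustive frame, no guards: everything with tops in the section counts
  cells <- data.frame(x = runif(200, 0.01, 99.9), y = runif(200, 0.01, 99.9),
                      z = runif(200, 0.01, 29.9))
  expect_equal(apply_counting_rules(cells, frame, guard = 0, depth = 30), 200)
})

test_that("Cavalieri volume follows the section-area formula", {
  expect_equal(cavalieri_volume(c(1e5, 1e5), interval = 4, thickness = 30),
               2.4e7)
  expect_equal(cavalieri_volume(numeric(0), 4, 30), 0)
  expect_error(cavalieri_volume(c(-1, 2), 4, 30), "non-negative")
})

test_that("fractionator and Cavalieri are unbiased on synthetic tissue", {
  # scaled-down replicate check (the full 200-replicate run is in the
  # acceptance suite): the paper design on a uniform box
  n_rep <- 40
  est <- vapply(seq_len(n_rep), function(s) {
    tp <- synth_tissue_params(true_N = c(NeuN = 400),
                              region_extent = c(400, 400, 600), seed = s)
    g <- gen_tissue_and_sample(tp, suppressWarnings(fractionator_design()))
    unname(suppressWarnings(
      fractionator_estimate(g$counts, fractionator_design())))
  }, numeric(1L))
  expect_equal(mean(est) / 400, 1, tolerance = 0.07)
  # Cavalieri on an ellipsoid region, over random section offsets
  vols <- vapply(seq_len(n_rep), function(s) {
    tp <- synth_tissue_params(true_N = c(NeuN = 50),
                              region_extent = c(400, 400, 600),
                              region_shape = "ellipsoid", seed = s)
    g <- gen_tissue_and_sample(tp, suppressWarnings(fractionator_design()))
    cavalieri_volume(g$counts$region_area, 4, 30) / g$truth$volume
  }, numeric(1L))
  expect_equal(mean(vols), 1, tolerance = 0.05)
})
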