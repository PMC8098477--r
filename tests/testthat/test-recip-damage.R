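test_that("dose-symmetric order is 0, -d, +d, -2d, ... and has 41 images", {
  sc <- dose_symmetric_order(60, 3)
  expect_identical(nrow(sc), 41L)
  expect_equal(sc$angle[1:5], c(0, -3, 3, -6, 6))
  expect_identical(sc$n, 1:41)
  expect_equal(range(sc$angle), c(-60, 60))
  ## +-40 / 2 degrees also gives 41 images
  expect_identical(nrow(dose_symmetric_order(40, 2)), 41L)
})

test_that("assign_tilt computes crossing angles and the missing wedge", {
  cell <- study_cell()
  sc <- dose_symmetric_order(60, 3)
  ## identity orientation: reflections along b* cross at theta = 0
  at <- assign_tilt(rbind(c(0, 3, 0)), cell, diag(3), sc)
  expect_equal(at$theta, 0)
  expect_equal(at$tilt, 0)
  ## reflections along c* (beam axis) lie in the wedge
  at2 <- assign_tilt(rbind(c(0, 0, 4)), cell, diag(3), sc)
  expect_equal(abs(at2$theta), 90)
  expect_true(is.na(at2$n))
  ## a 45-degree crossing is captured by the 45-degree image
  q45 <- c(0, cos(pi / 4), -sin(pi / 4))
  ## rotate b* onto q45: use an orientation that maps (0,1,0) there
  R <- rbind(c(1, 0, 0), c(0, cos(pi / 4), sin(pi / 4)),
             c(0, -sin(pi / 4), cos(pi / 4)))
  at3 <- assign_tilt(rbind(c(0, 3, 0)), cell, R, sc)
  expect_equal(at3$theta, 45, tolerance = 1e-9)
  expect_equal(at3$tilt, 45)
})

test_that("intensity decay follows I = I0 exp(-(n b_rel) q^2 / 4) exactly", {
  ref <- oracle_reference()
  cfg <- recip_damage_config(mean_phase_error = 0, completeness = 1,
                             b_rel = 3)
  sim <- simulate_damaged_dataset(ref, cfg, seed = 42)
  ## undo the known origin shift, match to the reference and check the decay
  rs <- phase_shift(sim$rs, -sim$u_true)
  sh <- rs_match(ref, rs)
  sc <- dose_symmetric_order(60, 3)
  at <- assign_tilt(ref$hkl[sh$ia, , drop = FALSE], ref$cell,
                    sim$orientation, sc)
  q <- hkl_q(ref$hkl[sh$ia, , drop = FALSE], ref$cell)
  expected <- ref$I[sh$ia] * exp(-(at$n * 3) * q^2 / 4)
  expect_equal(rs$I[sh$ib], expected, tolerance = 1e-9)
  ## phases untouched at zero phase error
  expect_lt(max(abs(wrap_deg(rs$phase[sh$ib] - ref$phase[sh$ia]))), 1e-9)
})

test_that("log-decay regression recovers n*b_rel/4 within 1 percent", {
  ref <- oracle_reference()
  q <- hkl_q(ref$hkl, ref$cell)
  b_rel <- 2.5; n_img <- 17
  decayed <- ref$I * exp(-(n_img * b_rel) * q^2 / 4)
  fit <- stats::lm(log(decayed / ref$I) ~ I(q^2) + 0)
  slope <- -unname(coef(fit)[1])
  expect_equal(slope, n_img * b_rel / 4, tolerance = 0.01)
})

test_that("completeness targeting keeps the strongest reflections", {
  ref <- oracle_reference()
  cfg <- recip_damage_config(completeness = 0.2)
  sim <- simulate_damaged_dataset(ref, cfg, seed = 3)
  n_full <- nrow(enumerate_hkl(ref$cell, 3.3))
  expect_equal(n_reflections(sim$rs) / n_full, 0.2, tolerance = 0.005)
  expect_equal(completeness(sim$rs, 3.3, "P1"), 0.2, tolerance = 0.005)
})

test_that("phase-noise scaling gives the target mean absolute error", {
  ref <- oracle_reference()
  cfg <- recip_damage_config(mean_phase_error = 20, completeness = 1)
  errs <- unlist(lapply(1:6, function(s) {
    sim <- simulate_damaged_dataset(ref, cfg, seed = 100 + s)
    rs <- phase_shift(sim$rs, -sim$u_true)
    sh <- rs_match(ref, rs)
    abs(wrap_deg(rs$phase[sh$ib] - ref$phase[sh$ia]))
  }))
  expect_equal(mean(errs), 20, tolerance = 0.05 * 20)
})

test_that("JS distance diagnostics match the oracles", {
  ## uniform coverage of the full +-60 range -> 0
  expect_equal(js_distance(seq(-60, 60, by = 1)), 0, tolerance = 1e-12)
  ## uniform +-40 inside a +-60 reference: closed form (independent oracle)
  expect_equal(js_distance(seq(-40, 40, by = 1)), 0.4348058483226871,
               tolerance = 1e-9)
  ## all mass in one bin is the most uneven case observed
  one <- js_distance(rep(0, 50))
  expect_gt(one, js_distance(rep(c(-30, 30), 25)))
  expect_lte(one, 1)
  ## empty input -> 1 by convention
  expect_equal(js_distance(numeric(0)), 1)
  expect_equal(js_distance(NA_real_), 1)
})

test_that("simulated data sets report their tilt-spread JS distance", {
  ref <- oracle_reference()
  sim <- simulate_damaged_dataset(ref, recip_damage_config(completeness = 0.4),
                                  seed = 9)
  expect_equal(sim$js, js_distance(sim$rs$tilt), tolerance = 1e-12)
  expect_true(sim$js > 0 && sim$js < 1)
})

test_that("sweep table is deterministic in the master seed and well-formed", {
  ref <- oracle_reference()
  s1 <- merging_success_sweep(ref, phase_errors = c(0, 20),
                              completenesses = 0.3, b_rels = 0,
                              pairs_per_condition = 1, seed = 77)
  s2 <- merging_success_sweep(ref, phase_errors = c(0, 20),
                              completenesses = 0.3, b_rels = 0,
                              pairs_per_condition = 1, seed = 77)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 2L)
  expect_true(all(c("common_ok", "single_ok_a", "single_ok_b", "merged_ok",
                    "js_a", "js_b") %in% names(s1)))
  ## noiseless, moderately complete pairs must succeed on every strategy
  noiseless <- s1[s1$phase_error == 0, ]
  expect_true(all(noiseless$common_ok, noiseless$single_ok_a,
                  noiseless$single_ok_b, noiseless$merged_ok))
  rates <- sweep_success_rates(s1)
  expect_equal(rates$rate_common - rates$rate_single,
               rates$common_minus_single / 100, tolerance = 1e-12)
})
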