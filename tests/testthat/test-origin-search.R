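test_that("symmetry and centric residuals vanish at crystallographic origins", {
  rs <- oracle_reference()
  expect_lt(symmetry_phase_residual(rs), 1e-6)
  expect_lt(centric_residual(rs), 1e-6)
  ## all eight permissible origins are equivalent
  for (i in 1:8) {
    u <- permissible_origins(rs$sg)$points[i, ]
    expect_lt(symmetry_phase_residual(rs, -u), 1e-6)
    expect_lt(centric_residual(rs, -u), 1e-6)
  }
  ## a generic origin is strongly penalized
  expect_gt(symmetry_phase_residual(rs, c(0.13, 0.29, 0.41)), 20)
  expect_gt(centric_residual(rs, c(0.13, 0.29, 0.41)), 20)
})

test_that("residual metrics return NA when uninformative", {
  rs <- oracle_reference()
  p1 <- reflection_set(rs$hkl, rs$I, rs$phase, rs$cell, "P1")
  expect_true(is.na(symmetry_phase_residual(p1)))
  expect_true(is.na(centric_residual(p1)))
  ## acentric-only subset of a P21 set has no centrics
  cellm <- unit_cell(16.2, 29.1, 47.7, 90, 95, 90)
  mod <- generate_pseudo_structure(2, 4, cellm, "P21")
  rm_ <- structure_factors(mod, cellm, "P21", 4)
  ci <- centric_info(rm_$hkl, rm_$sg)
  ac <- rs_subset(rm_, which(!ci$centric))
  expect_true(is.na(centric_residual(ac)))
})

test_that("symmetry_mean_phase transports equivalents onto the reflection", {
  rs <- oracle_reference()
  h <- rs$hkl[50, ]
  expect_equal(wrap_deg(symmetry_mean_phase(rs, h) - rs$phase[50]), 0,
               tolerance = 1e-6)
  ## unobserved reflection errors
  expect_error(symmetry_mean_phase(rs_subset(rs, 1:5), c(9, 9, 9)),
               "no observed")
})

test_that("map_skew is origin-discriminating after symmetry averaging", {
  rs <- oracle_reference()
  good <- map_skew(rs)
  bad <- map_skew(rs, c(0.17, 0.31, 0.07))
  expect_lt(good, bad)   # lower (more negative) skew score at the true origin
  expect_error(map_skew(rs_subset(rs, 1:5)), "at least 10")
})

test_that("find_crystallographic_origin recovers a shifted noiseless set", {
  rs <- oracle_reference()
  u_true <- c(0.31, 0.07, 0.62)
  shifted <- phase_shift(rs, u_true)
  res <- find_crystallographic_origin(shifted, interval = 0.2)
  ## u + u_true must land on a permissible origin within the sampling step
  expect_lt(origin_set_distance(res$u + u_true, rs$sg), 0.013)
  expect_s3_class(res$scores, "data.frame")
})

test_that("hierarchical and exhaustive origin search agree on a coarse grid", {
  rs <- oracle_reference()
  set.seed(5)
  sub <- rs_subset(rs, sort(sample.int(nrow(rs$hkl), 300)))
  shifted <- phase_shift(sub, c(0.5, 0.25, 0.75))
  h <- find_crystallographic_origin(shifted, interval = 1.5)
  e <- find_crystallographic_origin(shifted, interval = 1.5,
                                    method = "exhaustive")
  expect_equal(h$u, e$u, tolerance = 1e-12)
})

test_that("origin search edge cases behave as documented", {
  rs <- oracle_reference()
  p1 <- reflection_set(rs$hkl, rs$I, rs$phase, rs$cell, "P1")
  res <- find_crystallographic_origin(p1)
  expect_equal(res$u, c(0, 0, 0))
  expect_match(res$note, "P1")
  ## single acentric orphan reflections: no pairs, no centrics -> error
  one <- reflection_set(rbind(c(1, 2, 3)), 5, 10, rs$cell, "P212121")
  expect_error(find_crystallographic_origin(one), "not determinable")
})

test_that("origin search tolerates moderate phase noise", {
  rs <- oracle_reference()
  set.seed(31)
  noisy <- rs
  noisy$phase <- wrap_deg(rs$phase + rnorm(nrow(rs$hkl), 0, 20 * sqrt(pi / 2)))
  u_true <- runif(3)
  shifted <- phase_shift(noisy, u_true)
  res <- find_crystallographic_origin(shifted, interval = 0.2)
  expect_lt(origin_set_distance(res$u + u_true, rs$sg), 0.03)
})

test_that("reduce_to_asu groups orbits and preserves information", {
  rs <- oracle_reference()
  asu <- reduce_to_asu(rs)
  ## unique representatives; multiplicities sum to the input count
  expect_identical(anyDuplicated(apply(asu$hkl, 1, paste, collapse = " ")), 0L)
  expect_equal(sum(asu$mult), nrow(rs$hkl))
  ## representatives are their own ASU image
  am <- asu_map(asu$hkl, rs$sg)
  expect_equal(am$rep, asu$hkl, ignore_attr = TRUE)
  ## phases and intensities of a noiseless symmetric set are preserved:
  ## transported phase equals the original phase of each representative
  sh <- rs_match(asu, rs)
  expect_lt(max(abs(wrap_deg(asu$phase[sh$ia] - rs$phase[sh$ib]))), 1e-6)
  expect_equal(asu$I[sh$ia], rs$I[sh$ib], tolerance = 1e-9)
  ## reducing a shifted set at its recovered origin is consistent
  u <- c(0.5, 0, 0.5)
  asu2 <- reduce_to_asu(phase_shift(rs, u), -u)
  expect_phase_equal(asu2$phase, asu$phase)
})
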