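test_that("extract_peak recovers intensity and phase of an injected peak", {
  ctr <- c(20.3, 33.6, 41.1)
  fv <- inject_peaks(centers = rbind(ctr), volumes = 800, phases = 42)
  pred <- ctr - 1 - fv$center   # 0-based offset of the injected center
  res <- extract_peak(fv, c(1, 2, 3), pred)
  expect_true(res$accepted)
  ## the background floor is subtracted; the Gaussian volume is recovered
  expect_equal(res$intensity, 800, tolerance = 0.05 * 800)
  expect_equal(res$phase, 42, tolerance = 1)
  expect_lt(res$phase_std, 15)
  expect_equal(res$centroid, pred, tolerance = 0.3)
  expect_identical(res$h, c(1, 2, 3))
})

test_that("displaced peaks are rejected with reason partial", {
  ctr <- c(30, 30, 30)
  fv <- inject_peaks(centers = rbind(ctr), volumes = 800, phases = 0)
  pred_off <- (ctr - 1 - fv$center) + c(3, 2, 2)   # > 2 voxels away
  res <- extract_peak(fv, c(1, 0, 0), pred_off)
  expect_false(res$accepted)
  expect_identical(res$reason, "partial")
})

test_that("featureless regions and edges are rejected with their reasons", {
  fv <- inject_peaks(centers = rbind(c(30, 30, 30)), volumes = 800, phases = 0)
  flat <- extract_peak(fv, c(0, 1, 0), c(15, -15, 10))
  expect_false(flat$accepted)
  expect_identical(flat$reason, "no_peak")
  edge <- extract_peak(fv, c(0, 0, 1), c(31, 0, 0))   # subvolume leaves grid
  expect_false(edge$accepted)
  expect_identical(edge$reason, "edge")
})

test_that("an outlier pixel at 17 degrees among -161-degree neighbors is dropped", {
  ## the reference scenario: the peak phase is near -161 degrees; one pixel
  ## reads 17 degrees (nearly antiphase) and must be discarded by the
  ## 15-degree phase-spread rule, leaving the consensus phase untouched
  ctr <- c(30, 30, 30)
  fv <- inject_peaks(centers = rbind(ctr), volumes = 800, phases = -161,
                     bg_level = 0.01)
  out_idx <- c(31, 30, 30)
  fv$F[out_idx[1], out_idx[2], out_idx[3]] <-
    Mod(fv$F[out_idx[1], out_idx[2], out_idx[3]]) * exp(1i * 17 * pi / 180)
  pred <- ctr - 1 - fv$center
  res <- extract_peak(fv, c(1, 1, 1), pred)
  expect_true(res$accepted)
  expect_equal(res$phase, -161, tolerance = 1)
  expect_lte(res$phase_std, 15)
  ## without the removal rule the spread would be far above the threshold
  sub <- extract_peak(fv, c(1, 1, 1), pred,
                      extraction_config(phase_std_max = 180))
  expect_gt(sub$phase_std, 15)
})

test_that("incoherent phases are rejected", {
  set.seed(9)
  ctr <- c(30, 30, 30)
  fv <- inject_peaks(centers = rbind(ctr), volumes = 800, phases = 0,
                     bg_level = 0.01)
  ## scramble all phases in the peak region
  idx <- lapply(1:3, function(i) (ctr[i] - 4):(ctr[i] + 4))
  fv$F[idx[[1]], idx[[2]], idx[[3]]] <-
    Mod(fv$F[idx[[1]], idx[[2]], idx[[3]]]) *
    exp(1i * array(runif(9^3, -pi, pi), c(9, 9, 9)))
  res <- extract_peak(fv, c(1, 1, 1), ctr - 1 - fv$center)
  expect_false(res$accepted)
  expect_identical(res$reason, "phase_incoherent")
})

test_that("predict_peaks maps Miller indices to voxels and flags the wedge", {
  cell <- study_cell()
  dq <- rep(1 / 170, 3)
  A <- t(reciprocal_basis(cell))     # axis-aligned solution
  sol <- structure(list(A = A, cell = cell), class = "indexing_solution")
  pk <- predict_peaks(sol, dq, d_min = 3.3, tilt_range = 60)
  expect_identical(nrow(pk), nrow(enumerate_hkl(cell, 3.3)))
  ## voxel positions reproduce q = h A / dq
  i <- which(pk$h == 1 & pk$k == 2 & pk$l == 3)
  expect_equal(c(pk$x[i], pk$y[i], pk$z[i]),
               as.vector(c(1, 2, 3) %*% A) / dq, tolerance = 1e-9)
  ## reflections along c* lie in the wedge; along b* they do not
  expect_true(pk$in_wedge[pk$h == 0 & pk$k == 0][1])
  expect_false(pk$in_wedge[pk$h == 0 & pk$l == 0][1])
})

test_that("collect_reflections folds Friedel mates and carries tilt", {
  cell <- study_cell()
  obs <- list(
    list(h = c(1, 2, 3), accepted = TRUE, reason = NA, intensity = 10,
         phase = 40, phase_std = 3, centroid = c(0, 0, 0), n_pixels = 5L),
    list(h = c(-1, -2, -3), accepted = TRUE, reason = NA, intensity = 12,
         phase = -38, phase_std = 3, centroid = c(0, 0, 0), n_pixels = 5L),
    list(h = c(2, 0, 1), accepted = FALSE, reason = "partial",
         intensity = NA, phase = NA, phase_std = NA,
         centroid = rep(NA_real_, 3), n_pixels = 0L))
  expect_warning(rs <- collect_reflections(obs, cell, "P212121",
                                           tilt = c(10, -20, 5)),
                 "duplicate")
  expect_identical(nrow(rs$hkl), 1L)
  expect_identical(as.vector(rs$hkl[1, ]), c(1L, 2L, 3L))
  ## Friedel mate conjugated to +39 average, intensities averaged
  expect_equal(rs$I, 11)
  expect_equal(rs$phase, 39, tolerance = 0.5)
})
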