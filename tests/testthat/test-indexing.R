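## analytic spot list: reciprocal lattice points of a rotated cell, expressed
## as voxel offsets for a given reciprocal voxel size
synthetic_spots <- function(cell, R, dq, d_min = 2.5, jitter = 0,
                            tilt_wedge = 60, seed = 1) {
  set.seed(seed)
  hkl <- enumerate_hkl(cell, d_min, friedel_unique = FALSE)
  B <- reciprocal_basis(cell)
  S <- t(R %*% (B %*% t(hkl)))
  theta <- atan2(-S[, 3], S[, 2]) * 180 / pi
  theta <- theta - 180 * round(theta / 180)
  S <- S[abs(theta) <= tilt_wedge, , drop = FALSE]
  if (jitter > 0) S <- S + matrix(rnorm(length(S), 0, jitter), ncol = 3)
  data.frame(x = S[, 1] / dq[1], y = S[, 2] / dq[2], z = S[, 3] / dq[3],
             intensity = runif(nrow(S), 50, 500),
             n_pixels = 8L, d = 1 / sqrt(rowSums(S^2)))
}

same_cell <- function(got, want, tol = 0.02) {
  all(abs(sort(unlist(got[c("a", "b", "c")])) -
          sort(unlist(want[c("a", "b", "c")]))) <
        tol * sort(unlist(want[c("a", "b", "c")])))
}

test_that("find_spots locates injected Gaussian peaks", {
  d <- c(48, 48, 48)
  arr <- array(0, d)
  centers <- rbind(c(10, 20, 30), c(30, 12, 8), c(40, 40, 24))
  for (r in seq_len(nrow(centers))) {
    cc <- centers[r, ]
    for (i in -2:2) for (j in -2:2) for (k in -2:2)
      arr[cc[1] + i, cc[2] + j, cc[3] + k] <-
        50 * exp(-(i^2 + j^2 + k^2) / 2)
  }
  arr <- arr + 0.01 * array(runif(prod(d)), d)
  ## build a fourier_volume by hand: sqrt of intensity = |F|
  fv <- structure(list(F = arr + 0i, dq = c(0.01, 0.01, 0.01),
                       center = c(24L, 24L, 24L), voxel = 1),
                  class = "fourier_volume")
  spots <- find_spots(fv, gain = 6, beam_radius = 1)
  expect_identical(nrow(spots), 3L)
  found <- sweep(as.matrix(spots[, c("x", "y", "z")]), 2, -fv$center - 1)
  ord <- order(found[, 1])
  expect_equal(found[ord, ], centers[order(centers[, 1]), ],
               tolerance = 0.05, ignore_attr = TRUE)
  ## all centroids lie outside the beam-exclusion radius
  expect_true(all(sqrt(spots$x^2 + spots$y^2 + spots$z^2) > 1))
})

test_that("index_lattice recovers a randomly rotated orthorhombic cell", {
  cell <- study_cell()
  dq <- rep(1 / 170, 3)
  for (seed in 1:3) {
    set.seed(seed)
    R <- random_rotation()
    spots <- synthetic_spots(cell, R, dq, d_min = 3, jitter = 2e-4,
                             seed = seed)
    sol <- index_lattice(spots, dq)
    expect_true(same_cell(sol$cell, cell), label = paste("seed", seed))
    expect_lt(sol$residual, 0.05)
  }
})

test_that("refine_cell_symmetry projects onto the lattice constraints", {
  cell <- study_cell()
  dq <- rep(1 / 170, 3)
  set.seed(4)
  R <- random_rotation()
  spots <- synthetic_spots(cell, R, dq, d_min = 3, jitter = 3e-4, seed = 4)
  sol <- index_lattice(spots, dq)
  ref <- refine_cell_symmetry(sol, "P212121")
  expect_equal(ref$cell$alpha, 90)
  expect_equal(ref$cell$beta, 90)
  expect_equal(ref$cell$gamma, 90)
  expect_true(same_cell(ref$cell, cell, tol = 0.01))
  expect_lt(ref$residual, 0.05)
  ## wrong lattice system is rejected loudly
  tric <- unit_cell(10, 12, 14, 80, 95, 103)
  spots_t <- synthetic_spots(tric, diag(3), dq, d_min = 2.5, seed = 5)
  sol_t <- index_lattice(spots_t, dq, period_range = c(7, 30))
  expect_error(refine_cell_symmetry(sol_t, "P212121"), "constraint violation")
})

test_that("assigned Miller indices reproduce the spot positions", {
  cell <- study_cell()
  dq <- rep(1 / 170, 3)
  set.seed(6)
  spots <- synthetic_spots(cell, random_rotation(), dq, d_min = 3, seed = 6)
  sol <- index_lattice(spots, dq)
  frac <- sol$S %*% solve(sol$A)
  expect_lt(max(abs(frac - sol$hkl)), 0.2)
})

test_that("lattice_reduce undoes integer recombination of a basis", {
  M0 <- diag(c(16.2, 29.1, 47.7))
  M <- M0
  M[2, ] <- M[2, ] + M[1, ]            # b + a
  M[3, ] <- M[3, ] + 2 * M[1, ] - M[2, ]
  red <- tomoxtal:::lattice_reduce(M)
  expect_equal(abs(det(red)), abs(det(M0)), tolerance = 1e-9)
  expect_equal(sort(sqrt(rowSums(red^2))), c(16.2, 29.1, 47.7),
               tolerance = 1e-9)
  expect_gt(det(red), 0)
})

test_that("gcd_reduce_columns removes harmonic index doubling", {
  H <- rbind(c(2, 1, 3), c(4, 0, -3), c(-6, 2, 0))
  expect_identical(tomoxtal:::gcd_reduce_columns(H),
                   rbind(c(1, 1, 1), c(2, 0, -1), c(-3, 2, 0)))
  ## columns with no common factor are untouched
  H2 <- rbind(c(1, 2, 3), c(2, 3, 4))
  expect_identical(tomoxtal:::gcd_reduce_columns(H2), H2)
})

test_that("degenerate spot lists are rejected", {
  dq <- rep(0.01, 3)
  flat <- data.frame(x = 1:10, y = (1:10) * 2, z = 0, intensity = 1,
                     n_pixels = 5L, d = 10)
  expect_error(index_lattice(flat, dq), "degenerate")
  few <- data.frame(x = 1:3, y = c(4, 1, 7), z = c(2, 8, 3), intensity = 1,
                    n_pixels = 5L, d = 10)
  expect_error(index_lattice(few, dq), "degenerate")
})
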