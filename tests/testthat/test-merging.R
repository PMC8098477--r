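test_that("phase_shift applies the translation theorem and is invertible", {
  rs <- oracle_reference()
  u <- c(0.21, -0.4, 0.125)
  sh <- phase_shift(rs, u)
  expect_equal(sh$phase,
               wrap_deg(rs$phase - 360 * as.vector(rs$hkl %*% u)))
  expect_equal(sh$I, rs$I)
  back <- phase_shift(sh, -u)
  expect_equal(wrap_deg(back$phase - rs$phase), rep(0, nrow(rs$hkl)),
               tolerance = 1e-9)
  ## integer shifts are the identity (modulo 360)
  expect_phase_equal(phase_shift(rs, c(1, 2, -1))$phase, rs$phase)
})

test_that("origin_grid_dims spacing is at least as fine as requested", {
  dims <- origin_grid_dims(study_cell(), 0.2)
  lens <- c(16.2, 29.1, 47.7)
  expect_true(all(lens / dims <= 0.2))
  ## 5-smooth dimensions
  smooth <- function(n) { for (p in c(2, 3, 5)) while (n %% p == 0) n <- n / p; n == 1 }
  expect_true(all(vapply(dims, smooth, logical(1))))
})

test_that("origin_alignment recovers exact grid-resolvable shifts (noiseless)", {
  rs <- oracle_reference()
  dims <- origin_grid_dims(rs$cell, 0.2)
  u_true <- c(7, 13, 40) / dims
  other <- phase_shift(rs, u_true)
  al <- origin_alignment(rs, other, interval = 0.2)
  expect_equal(merge_error(al$u, -u_true), 0, tolerance = 1e-12)
  expect_lt(al$residual, 1e-6)
  expect_equal(al$n_shared, nrow(rs$hkl))
  ## the shifted copy is back on the reference origin
  expect_lt(max(abs(wrap_deg(al$shifted$phase - rs$phase))), 1e-6)
})

test_that("fft and exhaustive alignment agree", {
  rs <- oracle_reference()
  set.seed(11)
  sub <- rs_subset(rs, sample.int(nrow(rs$hkl), 200))
  u_true <- c(0.25, 0.4, 0.1)
  other <- phase_shift(sub, u_true)
  other$phase <- wrap_deg(other$phase + rnorm(200, 0, 15))
  a1 <- origin_alignment(rs, other, interval = 0.4, method = "fft")
  a2 <- origin_alignment(rs, other, interval = 0.4, method = "exhaustive")
  expect_equal(a1$u, a2$u, tolerance = 1e-12)
  expect_equal(a1$residual, a2$residual, tolerance = 1e-9)
})

test_that("alignment degenerate inputs raise conditions", {
  rs <- oracle_reference()
  a <- rs_subset(rs, 1:10)
  b <- rs_subset(rs, 400:420)
  expect_error(origin_alignment(a, b), "shared")
  two <- rs_subset(rs, 1:2)
  expect_warning(origin_alignment(two, two, interval = 2), "fewer than 3")
})

test_that("scale_intensities recovers an injected Debye-Waller width", {
  rs <- oracle_reference()
  q <- hkl_q(rs$hkl, rs$cell)
  s <- 2.5
  other <- rs
  other$I <- rs$I * exp(-q^2 * s^2 / 2)
  fit <- scale_intensities(rs, other)
  expect_equal(fit$params$sigma, s, tolerance = 0.05 * s)
  ## rescaled intensities match the reference
  expect_equal(fit$scaled$I, rs$I, tolerance = 1e-6)
  ## constant scale factor: b recovered, sigma ~ 0
  other2 <- rs
  other2$I <- 2 * rs$I
  fit2 <- scale_intensities(rs, other2)
  expect_equal(fit2$params$b, log(2), tolerance = 1e-9)
  expect_lt(fit2$params$sigma, 1e-6)
})

test_that("merge_datasets aligns, averages and counts multiplicities", {
  rs <- oracle_reference()
  set.seed(21)
  ia <- sort(sample.int(nrow(rs$hkl), 700))
  ib <- sort(sample.int(nrow(rs$hkl), 700))
  a <- rs_subset(rs, ia)
  ## a shift on the 0.2-Angstrom alignment grid (dims 81, 150, 240), so the
  ## noiseless search can recover it exactly
  b <- phase_shift(rs_subset(rs, ib), c(20 / 81, 30 / 150, 100 / 240))
  mg <- merge_datasets(list(a, b), interval = 0.2)
  m <- mg$merged
  ## every input reflection present exactly once
  expect_identical(sort(unique(c(ia, ib))),
                   sort(match(apply(m$hkl, 1, paste, collapse = " "),
                              apply(rs$hkl, 1, paste, collapse = " "))))
  ## multiplicity 2 exactly for the overlap
  overlap <- intersect(ia, ib)
  key_m <- apply(m$hkl, 1, paste, collapse = " ")
  key_o <- apply(rs$hkl[overlap, , drop = FALSE], 1, paste, collapse = " ")
  expect_equal(sort(m$mult[match(key_o, key_m)]), rep(2, length(overlap)))
  ## phases agree with the reference origin (noiseless alignment)
  expect_lt(max(abs(wrap_deg(m$phase - rs$phase[match(key_m,
    apply(rs$hkl, 1, paste, collapse = " "))]))), 1e-6)
})

test_that("merge of disjoint sets errors", {
  rs <- oracle_reference()
  expect_error(merge_datasets(list(rs_subset(rs, 1:50), rs_subset(rs, 100:150))),
               "share no reflections|shared")
})

test_that("merge_error is a minimal-image metric", {
  expect_equal(merge_error(c(0.98, 0, 0), c(-0.02, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(merge_error(c(0.5, 0.5, 0.5), c(0, 0, 0)),
               sqrt(0.75), tolerance = 1e-12)
  expect_equal(merge_error(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0)
})
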