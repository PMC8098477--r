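## Shared fixtures for the test suite.

## independent wrap-to-(-90,90] helper (re-implemented here on purpose)
wrap_half_deg_test <- function(x) {
  w <- x %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

## the orthorhombic study cell used throughout
study_cell <- function() unit_cell(16.2, 29.1, 47.7)

## fixed two-atom Gaussian model (coordinates frozen; independently oracled)
oracle_model <- function(sg = "P212121") {
  expand_atoms(data.frame(x = c(0.12, 0.55), y = c(0.37, 0.21),
                          z = c(0.81, 0.33), w = c(9, 12),
                          sigma = c(1.1, 0.9)), sg)
}

## reference structure factors reused by several files (computed once)
oracle_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- structure_factors(oracle_model(), study_cell(), "P212121", 3.3)
    cache
  }
})

## small tomogram scenario: pseudo-structure crystal, dose-symmetric tilt
## series, weighted-back-projection tomogram (slow-ish; computed once)
small_tomogram <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(7)
      cell <- unit_cell(10, 12, 14)
      model <- generate_pseudo_structure(5, 4, cell, "P212121")
      vol <- build_crystal_density(model, cell, 0.8, n_cells = c(4, 4, 3))
      vol <- embed_crystal(vol)
      scheme <- dose_symmetric_order(60, 3)
      ts <- damaged_tilt_series(vol, scheme)
      cache <<- list(
        tomo = reconstruct_tomogram(ts$projections, ts$angles, 0.8),
        model = model, cell = cell, sg = "P212121")
    }
    cache
  }
})

## angular equality: compares phase vectors modulo 360 degrees, so that
## +180 vs -180 and 0 vs -0 (floating-point sign) count as equal
expect_phase_equal <- function(actual, expected, tol = 1e-6) {
  d <- (actual - expected) %% 360
  d[d > 180] <- d[d > 180] - 360
  testthat::expect_lt(max(abs(d)), tol)
}

## build a fourier_volume with injected complex Gaussian peaks on a noisy
## background; returns the volume and the injected truth
inject_peaks <- function(dims = c(64, 64, 64), centers, volumes, phases,
                         width = 1.2, bg_level = 0.5, seed = 1) {
  set.seed(seed)
  amp <- array(bg_level * runif(prod(dims)), dims)
  ph <- array(0, dims)
  for (r in seq_len(nrow(centers))) {
    cc <- centers[r, ]
    rng <- lapply(1:3, function(i) {
      v <- (round(cc[i]) - 5):(round(cc[i]) + 5)
      v[v >= 1 & v <= dims[i]]
    })
    for (i in rng[[1]]) for (j in rng[[2]]) for (k in rng[[3]]) {
      g <- volumes[r] / (2 * pi * width^2)^1.5 *
        exp(-((i - cc[1])^2 + (j - cc[2])^2 + (k - cc[3])^2) / (2 * width^2))
      amp[i, j, k] <- amp[i, j, k] + g
      ph[i, j, k] <- phases[r]
    }
  }
  structure(list(F = sqrt(amp) * exp(1i * ph * pi / 180),
                 dq = rep(0.01, 3),
                 center = as.integer(floor(dims / 2)), voxel = 1),
            class = "fourier_volume")
}
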