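## Tomogram preprocessing: edge taper, density centering, Fourier transform
## with a grid-centered phase origin, and the phase-splitting diagnostic.

## circular shift of a 3D array by integer steps (positive = towards higher
## indices)
shift_array <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(i) ((seq_len(d[i]) - 1 - s[i]) %% d[i]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

## 1D Tukey window: total tapered fraction `fraction` (half at each end)
tukey_window <- function(n, fraction) {
  if (fraction <= 0) return(rep(1, n))
  w <- rep(1, n)
  m <- fraction * (n - 1) / 2
  x <- seq(0, n - 1)
  lo <- x < m
  hi <- x > n - 1 - m
  w[lo] <- 0.5 * (1 + cos(pi * (x[lo] / m - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((n - 1 - x[hi]) / m - 1)))
  w
}

#' Taper the edges of a volume
#'
#' Applies a separable Tukey (tapered-cosine) window along each axis to
#' suppress the sharp edges of a reconstructed tomogram before Fourier
#' analysis.
#'
#' @param vol a `volume`.
#' @param fraction total tapered fraction per axis (default 0.5).
#' @return the tapered `volume`.
#' @export
taper <- function(vol, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  d <- vol_dims(vol)
  w1 <- tukey_window(d[1], fraction)
  w2 <- tukey_window(d[2], fraction)
  w3 <- tukey_window(d[3], fraction)
  arr <- vol$data * as.vector(w1) *
    rep(w2, each = d[1]) *
    rep(w3, each = d[1] * d[2])
  volume(array(arr, d), vol$voxel)
}

#' Center a density in its grid
#'
#' Estimates the density's center of symmetry from the peak of the
#' auto-convolution (computed as the inverse transform of the squared Fourier
#' transform, which peaks at twice the center position) and circularly shifts
#' the volume so that point sits on the central voxel. The half-grid
#' ambiguity of the half-peak position is resolved by picking the candidate
#' nearer the center of mass.
#'
#' @param vol a `volume`.
#' @return list with `vol` (the centered `volume`) and `shift` (the integer
#'   voxel shift that was applied).
#' @export
center_density <- function(vol) {
  d <- vol_dims(vol)
  f <- vol$data - min(vol$data)
  if (sum(f) == 0)            # featureless volume: nothing to center
    return(list(vol = vol, shift = c(0L, 0L, 0L)))
  Fh <- stats::fft(f)
  conv <- Re(stats::fft(Fh * Fh, inverse = TRUE))
  m <- arrayInd(which.max(conv), d) - 1L           # peak at ~ 2 * center
  com <- vapply(1:3, function(i) {
    w <- apply(f, i, sum)
    sum((seq_len(d[i]) - 1) * w) / sum(w)
  }, numeric(1))
  ## two half-grid candidates per axis: m/2 and m/2 + d/2
  ctr <- vapply(1:3, function(i) {
    cand <- (m[i] / 2 + c(0, d[i] / 2)) %% d[i]
    cand[which.min(abs(cand - com[i]))]
  }, numeric(1))
  target <- floor(d / 2)
  ## floor(x + 0.5) is consistent under integer translation of the input
  ## (round() half-to-even is not), so re-centering a shifted copy undoes
  ## the shift exactly
  s <- as.integer(floor(target - ctr + 0.5))
  out <- volume(shift_array(vol$data, s), vol$voxel)
  list(vol = out, shift = s)
}

#' Fourier transform of a volume with a grid-centered origin
#'
#' Computes the discrete Fourier transform with the real-space phase origin
#' on the central voxel (`floor(dims / 2)`, 0-based) and the zero-frequency
#' term moved to the central element of the output grid, so Friedel mates sit
#' symmetrically about the array center.
#'
#' @param vol a `volume`.
#' @return an object of class `fourier_volume`: complex grid `F`, reciprocal
#'   voxel sizes `dq` (inverse Angstrom per voxel along each axis), and the
#'   0-based index `center` of the zero-frequency voxel.
#' @export
fourier_transform <- function(vol) {
  d <- vol_dims(vol)
  ctr <- as.integer(floor(d / 2))
  G <- stats::fft(shift_array(vol$data, -ctr))  # origin voxel -> index 1
  G <- shift_array(G, ctr)                      # zero frequency -> center
  structure(list(F = G, dq = 1 / (d * vol$voxel), center = ctr,
                 voxel = vol$voxel),
            class = "fourier_volume")
}

#' @export
print.fourier_volume <- function(x, ...) {
  d <- dim(x$F)
  cat(sprintf("fourier volume: %d x %d x %d, dq = (%.5f, %.5f, %.5f) A^-1\n",
              d[1], d[2], d[3], x$dq[1], x$dq[2], x$dq[3]))
  invisible(x)
}

#' Intensities of a Fourier volume
#' @param fv a `fourier_volume`.
#' @return numeric array `|F|^2`.
#' @export
fourier_intensity <- function(fv) Mod(fv$F)^2

#' Phases of a Fourier volume
#' @param fv a `fourier_volume`.
#' @return numeric array of phases in degrees in (-180, 180].
#' @export
fourier_phase <- function(fv) wrap_deg(Arg(fv$F) * 180 / pi)

#' Phase splitting across a 2x2x2 voxel block
#'
#' Bragg peaks of a tomogram rarely fall on integer voxels, so their phase is
#' spread over the adjacent voxels. This diagnostic takes the 2x2x2 block
#' whose lowest corner is `corner` (0-based voxel index) and returns the mean
#' absolute wrapped phase difference over the block's 12 edges (pairs of
#' corner neighbors differing in one index).
#'
#' @param fv a `fourier_volume`.
#' @param corner 0-based voxel index of the block's lowest corner.
#' @return mean absolute wrapped phase difference in degrees.
#' @export
phase_splitting_metric <- function(fv, corner) {
  d <- dim(fv$F)
  corner <- as.integer(corner)
  stopifnot(all(corner >= 0), all(corner + 2 <= d))
  ph <- fourier_phase(fv)[corner[1] + (1:2), corner[2] + (1:2),
                          corner[3] + (1:2)]
  edges <- rbind(
    cbind(expand.grid(i = 1:1, j = 1:2, k = 1:2),
          expand.grid(i = 2:2, j = 1:2, k = 1:2)),
    cbind(expand.grid(i = 1:2, j = 1:1, k = 1:2),
          expand.grid(i = 1:2, j = 2:2, k = 1:2)),
    cbind(expand.grid(i = 1:2, j = 1:2, k = 1:1),
          expand.grid(i = 1:2, j = 1:2, k = 2:2)))
  names(edges) <- c("i1", "j1", "k1", "i2", "j2", "k2")
  d12 <- apply(edges, 1, function(e)
    abs(wrap_deg(ph[e[1], e[2], e[3]] - ph[e[4], e[5], e[6]])))
  mean(d12)
}
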