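## Real-space crystal simulator: density of a finite crystal block, tilt
## series projection (beam along z, tilt axis along x), dose-dependent
## damage "hits", and weighted-back-projection reconstruction.

#' Sample the density of a finite crystal block
#'
#' Tiles the unit cell `n_cells` times along each axis and samples every
#' Gaussian scatterer onto an isotropic voxel grid. Requires an orthogonal
#' cell (grid axes coincide with cell axes).
#'
#' @param model atomic model (fractional `x`,`y`,`z`, weight `w`, width
#'   `sigma`), already symmetry-expanded (e.g. from
#'   [generate_pseudo_structure()]).
#' @param cell a `unit_cell` with 90-degree angles.
#' @param voxel voxel size in Angstrom; must not exceed the narrowest atom
#'   width or the density is undersampled.
#' @param n_cells integer 3-vector of unit-cell repeats.
#' @return a `volume` covering the crystal block.
#' @export
build_crystal_density <- function(model, cell, voxel, n_cells = c(2, 2, 1)) {
  if (max(abs(c(cell$alpha, cell$beta, cell$gamma) - 90)) > 1e-6)
    stop("real-space simulation requires an orthogonal cell")
  if (voxel > min(model$sigma))
    stop("undersampled: voxel size exceeds the narrowest atom width")
  len <- cell_lengths(cell) * n_cells
  dims <- pmax(2L, as.integer(ceiling(len / voxel)))
  arr <- array(0, dims)
  ## replicate atoms over the tiled cells, positions in Angstrom
  offs <- as.matrix(expand.grid(a = seq_len(n_cells[1]) - 1,
                                b = seq_len(n_cells[2]) - 1,
                                c = seq_len(n_cells[3]) - 1))
  frac <- as.matrix(model[, c("x", "y", "z")])
  r <- 4  # splat radius in sigmas
  for (o in seq_len(nrow(offs))) {
    pos <- sweep(frac, 2, offs[o, ], "+") %*% diag(cell_lengths(cell))
    for (a in seq_len(nrow(pos))) {
      s <- model$sigma[a]
      lo <- pmax(1L, as.integer(floor((pos[a, ] - r * s) / voxel)) + 1L)
      hi <- pmin(dims, as.integer(ceiling((pos[a, ] + r * s) / voxel)) + 1L)
      if (any(lo > hi)) next
      gx <- ((lo[1]:hi[1]) - 1) * voxel - pos[a, 1]
      gy <- ((lo[2]:hi[2]) - 1) * voxel - pos[a, 2]
      gz <- ((lo[3]:hi[3]) - 1) * voxel - pos[a, 3]
      g <- model$w[a] / ((2 * pi)^1.5 * s^3) *
        outer(outer(exp(-gx^2 / (2 * s^2)), exp(-gy^2 / (2 * s^2))),
              exp(-gz^2 / (2 * s^2)))
      arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + g
    }
  }
  volume(arr, voxel)
}

#' Embed a crystal block in a rotation-safe cube
#'
#' Pads the volume into a cube whose edge is 1.4 times the block diagonal, so
#' any 3D rotation keeps the crystal inside the grid. The original block
#' position is recorded in the `crystal_box` attribute (voxel index ranges).
#'
#' @param vol a `volume`.
#' @param pad_factor cube edge as a multiple of the block diagonal.
#' @return a cubic `volume`.
#' @export
embed_crystal <- function(vol, pad_factor = 1.4) {
  d <- vol_dims(vol)
  edge <- as.integer(ceiling(pad_factor * sqrt(sum(d^2))))
  out <- array(0, c(edge, edge, edge))
  lo <- as.integer(floor((edge - d) / 2)) + 1L
  hi <- lo + d - 1L
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- vol$data
  v <- volume(out, vol$voxel)
  attr(v, "crystal_box") <- rbind(lo = lo, hi = hi)
  v
}

#' Rotate a volume about its center
#'
#' @param vol a `volume`.
#' @param R 3x3 rotation matrix (object rotation).
#' @return the rotated `volume` (trilinear interpolation, zero fill).
#' @export
rotate_volume <- function(vol, R) {
  d <- vol_dims(vol)
  out <- cpp_rotate_vol(as.vector(vol$data), d[1], d[2], d[3], R)
  v <- volume(array(out, d), vol$voxel)
  attr(v, "crystal_box") <- attr(vol, "crystal_box")
  v
}

#' Project a tilt series
#'
#' Computes one projection image per tilt angle: the volume is rotated about
#' the x axis by the tilt angle and summed along the beam (z) axis.
#'
#' @param vol a `volume`.
#' @param angles tilt angles in degrees.
#' @return 3D array (nx x ny x n_tilt) of projection images.
#' @export
project_tilt_series <- function(vol, angles) {
  d <- vol_dims(vol)
  out <- array(0, c(d[1], d[2], length(angles)))
  for (i in seq_along(angles))
    out[, , i] <- cpp_project_x(as.vector(vol$data), d[1], d[2], d[3],
                                angles[i])
  out
}

#' Apply radiation-damage hits to a volume
#'
#' Each hit replaces a cubic subvolume of edge `2 * halfwidth` Angstrom
#' around a random site inside the crystal region with a Gaussian-blurred
#' copy of itself (`sigma` Angstrom per axis), locally smearing the density.
#' Sites are drawn uniformly from the `crystal_box` attribute when present,
#' otherwise from the whole volume (uses the current RNG state).
#'
#' @param vol a `volume`.
#' @param n_hits number of hits to apply.
#' @param halfwidth half the hit-box edge in Angstrom (default 2.5, i.e. a
#'   5 Angstrom box).
#' @param sigma blur standard deviation in Angstrom (default 1).
#' @return the damaged `volume`.
#' @export
apply_damage_hits <- function(vol, n_hits, halfwidth = 2.5, sigma = 1) {
  if (n_hits == 0) return(vol)
  d <- vol_dims(vol)
  box <- attr(vol, "crystal_box")
  if (is.null(box)) box <- rbind(lo = c(1L, 1L, 1L), hi = d)
  sites <- cbind(sample.int(box["hi", 1] - box["lo", 1] + 1L, n_hits, TRUE),
                 sample.int(box["hi", 2] - box["lo", 2] + 1L, n_hits, TRUE),
                 sample.int(box["hi", 3] - box["lo", 3] + 1L, n_hits, TRUE))
  sites <- sweep(sites, 2, box["lo", ] - 2L, "+")  # to 0-based volume indices
  hw <- max(1L, as.integer(round(halfwidth / vol$voxel)))
  out <- cpp_damage_hits(as.vector(vol$data), d[1], d[2], d[3], sites, hw,
                         sigma / vol$voxel)
  v <- volume(array(out, d), vol$voxel)
  attr(v, "crystal_box") <- attr(vol, "crystal_box")
  v
}

#' Project a tilt series with accumulating damage
#'
#' Follows the acquisition order of the tilt scheme: before each image,
#' `hits_per_image` fresh damage hits are applied to the (already damaged)
#' crystal, so the absorbed dose grows linearly across the series. Images are
#' returned in angle order with their acquisition indices.
#'
#' @param vol a `volume` (rotated crystal in its rotation-safe cube).
#' @param scheme tilt scheme from [dose_symmetric_order()].
#' @param hits_per_image damage hits added before each image.
#' @param ... passed to [apply_damage_hits()].
#' @return list with `projections` (nx x ny x n_tilt array, in `scheme`
#'   order), `angles` and `n` (acquisition indices).
#' @export
damaged_tilt_series <- function(vol, scheme, hits_per_image = 0, ...) {
  d <- vol_dims(vol)
  out <- array(0, c(d[1], d[2], nrow(scheme)))
  for (i in order(scheme$n)) {
    if (hits_per_image > 0) vol <- apply_damage_hits(vol, hits_per_image, ...)
    out[, , i] <- cpp_project_x(as.vector(vol$data), d[1], d[2], d[3],
                                scheme$angle[i])
  }
  list(projections = out, angles = scheme$angle, n = scheme$n)
}

#' Weighted back-projection reconstruction
#'
#' Reconstructs a tomogram from a tilt series about the x axis: each
#' projection is ramp-filtered along y (the axis perpendicular to the tilt
#' axis), back-projected, and the result scaled by `pi / (2 n_tilt)`.
#'
#' @param projections nx x ny x n_tilt array of projection images.
#' @param angles tilt angles in degrees (length n_tilt).
#' @param voxel voxel size in Angstrom of the output volume.
#' @param nz number of output slices along z (default ny).
#' @return a `volume` (nx x ny x nz).
#' @export
reconstruct_tomogram <- function(projections, angles, voxel, nz = NULL) {
  d <- dim(projections)
  stopifnot(length(d) == 3, d[3] == length(angles))
  if (is.null(nz)) nz <- d[2]
  ## ramp filter along y, applied per projection via FFT of each x-row
  ramp <- abs(seq(0, d[2] - 1) - d[2] * (seq(0, d[2] - 1) > d[2] / 2)) / d[2]
  filt <- array(0, d)
  for (t in seq_len(d[3])) {
    P <- t(stats::mvfft(t(projections[, , t])))       # FFT along y per x-row
    filt[, , t] <- Re(t(stats::mvfft(t(P * rep(ramp, each = d[1])),
                                     inverse = TRUE))) / d[2]
  }
  rec <- cpp_backproject(as.vector(filt), d[1], d[2], d[3], angles, nz)
  volume(array(rec * pi / (2 * d[3]), c(d[1], d[2], nz)), voxel)
}
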