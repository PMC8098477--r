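## Real-space volume container.

#' Real-space volume
#'
#' A 3D numeric array with an isotropic voxel size in Angstrom.
#'
#' @param data 3D numeric array.
#' @param voxel voxel edge length in Angstrom.
#' @return an object of class `volume`.
#' @export
volume <- function(data, voxel) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel > 0)
  structure(list(data = data, voxel = as.numeric(voxel)), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume: %d x %d x %d voxels, %.3f A/voxel (%.1f x %.1f x %.1f A)\n",
              d[1], d[2], d[3], x$voxel,
              d[1] * x$voxel, d[2] * x$voxel, d[3] * x$voxel))
  invisible(x)
}

#' Volume dimensions
#' @param vol a `volume`.
#' @return integer 3-vector of voxel counts.
#' @export
vol_dims <- function(vol) dim(vol$data)
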