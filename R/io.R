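## Minimal MRC (mode 2, 32-bit float) volume IO and tilt-angle text files.
## The MRC header is 1024 bytes; only the fields needed for density volumes
## are interpreted (dimensions, mode, sampling, cell lengths, map stamp).

#' Write a volume as an MRC file (mode 2)
#'
#' @param vol a `volume`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mrc <- function(vol, path) {
  d <- vol_dims(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2: 32-bit float
  wi(c(0, 0, 0))              # nxstart nystart nzstart
  wi(d)                       # mx my mz
  wf(d * vol$voxel)           # xlen ylen zlen
  wf(c(90, 90, 90))           # cell angles
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # dmin dmax dmean
  wi(c(0, 0))                 # ispg, nsymbt
  writeBin(raw(100), con)     # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vol$data))     # rms
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume (mode 2)
#'
#' @param path input file path.
#' @return a `volume`; the voxel size is derived from `xlen / mx`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  if (length(d) < 3 || any(!is.finite(d)) || any(d <= 0) || any(d > 1e5))
    stop("corrupt MRC header: field nx/ny/nz")
  mode <- ri(1)
  if (!identical(mode, 2L))
    stop("unsupported MRC mode (field mode): ", mode, "; only mode 2 is read")
  ri(3)                        # starts
  m <- ri(3)                   # mx my mz
  if (any(m <= 0)) stop("corrupt MRC header: field mx/my/mz")
  len <- rf(3)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("corrupt MRC header: field xlen/ylen/zlen")
  rf(3)                        # angles
  mapc <- ri(3)
  if (!identical(mapc, c(1L, 2L, 3L)))
    stop("unsupported axis order (field mapc/mapr/maps)")
  seek(con, 208)
  stamp <- readBin(con, "raw", 4)
  if (!identical(stamp, charToRaw("MAP ")))
    stop("corrupt MRC header: field map stamp")
  voxel <- len[1] / m[1]
  if (max(abs(len / m - voxel)) > 1e-4)
    stop("anisotropic voxel sizes are not supported")
  seek(con, 1024)
  n <- prod(d)
  data <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(data) < n) stop("truncated MRC data block")
  volume(array(data, d), voxel)
}

#' Write tilt angles to a text file
#'
#' One angle (degrees) per line, in acquisition order.
#'
#' @param angles numeric vector of tilt angles.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_tilt_angles <- function(angles, path) {
  writeLines(format(angles, trim = TRUE), path)
  invisible(path)
}

#' Read tilt angles from a text file
#'
#' @param path input file path.
#' @return numeric vector of tilt angles in degrees.
#' @export
read_tilt_angles <- function(path) {
  x <- suppressWarnings(as.numeric(readLines(path)))
  if (any(is.na(x))) stop("malformed tilt-angle file: non-numeric line")
  x
}
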