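#' Unit cell
#'
#' Construct a crystallographic unit cell from its six parameters.
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return an object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) stop("cell angles must lie in (0, 180)")
  cell <- structure(as.list(p), class = "unit_cell")
  O <- orthogonalization_matrix(cell)
  if (det(O) <= 0 || !is.finite(det(O)))
    stop("cell metric is not positive-definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

cell_lengths <- function(cell) c(cell$a, cell$b, cell$c)

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Returns the 3x3 matrix O such that Cartesian coordinates (Angstrom) are
#' `O %*% x_frac`, with the a axis along x (PDB convention).
#'
#' @param cell a `unit_cell`.
#' @return a 3x3 numeric matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("cell metric is not positive-definite")
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * sqrt(v) / sg),
         nrow = 3, byrow = TRUE)
}

#' Reciprocal basis matrix
#'
#' Columns are the reciprocal basis vectors a*, b*, c* in Cartesian Angstrom^-1,
#' so that the scattering vector of reflection h is `B %*% h`.
#'
#' @param cell a `unit_cell`.
#' @return a 3x3 numeric matrix.
#' @export
reciprocal_basis <- function(cell) {
  t(solve(orthogonalization_matrix(cell)))
}

#' Cell volume in cubic Angstrom
#' @param cell a `unit_cell`.
#' @return numeric scalar.
#' @export
cell_volume <- function(cell) det(orthogonalization_matrix(cell))

#' Magnitude of the scattering vector q = 1/d for reflections
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param cell a `unit_cell`.
#' @return numeric vector of |q| in Angstrom^-1.
#' @export
hkl_q <- function(hkl, cell) {
  hkl <- rbind(hkl, deparse.level = 0)
  B <- reciprocal_basis(cell)
  s <- hkl %*% t(B)
  unname(sqrt(rowSums(s^2)))
}

#' Resolution d = 1/q of reflections in Angstrom
#' @inheritParams hkl_q
#' @return numeric vector of d-spacings.
#' @export
hkl_d <- function(hkl, cell) 1 / hkl_q(hkl, cell)

#' Enumerate Miller indices to a resolution limit
#'
#' Lists all reflections with 1/|q| >= `d_min`, excluding (0,0,0). By default
#' only the Friedel-unique hemisphere is returned (l > 0, or l = 0 and k > 0,
#' or k = l = 0 and h > 0).
#'
#' @param cell a `unit_cell`.
#' @param d_min high-resolution limit in Angstrom.
#' @param friedel_unique keep only one member of each Friedel pair?
#' @return integer matrix (n x 3) of Miller indices.
#' @export
enumerate_hkl <- function(cell, d_min, friedel_unique = TRUE) {
  stopifnot(d_min > 0)
  lim <- ceiling(cell_lengths(unclass_cell(cell)) / d_min) + 1L
  g <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  hkl <- as.matrix(g)
  q <- hkl_q(hkl, cell)
  keep <- q > 0 & q <= 1 / d_min
  if (friedel_unique) {
    keep <- keep & (hkl[, 3] > 0 |
                    (hkl[, 3] == 0 & hkl[, 2] > 0) |
                    (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0))
  }
  m <- hkl[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("h", "k", "l"))
  m
}

unclass_cell <- function(cell) cell  # placeholder for future lattice variants

## cell parameters from a reciprocal basis matrix (columns a*, b*, c*)
cell_from_reciprocal <- function(B) {
  A <- t(solve(B))  # columns a, b, c in Cartesian
  len <- sqrt(colSums(A^2))
  ang <- function(i, j) acos(sum(A[, i] * A[, j]) / (len[i] * len[j])) * 180 / pi
  unit_cell(len[1], len[2], len[3], ang(2, 3), ang(1, 3), ang(1, 2))
}
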