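## Data-quality metrics: completeness, reference phase residuals, intensity
## and map correlations.

#' Completeness of a reflection set
#'
#' Fraction of the theoretically observable reflections to `d_min` that are
#' present. In "P1" mode the denominator is the full Friedel-unique count
#' (missing wedge included), before accounting for space-group symmetry; in
#' "sg" mode observed and theoretical reflections are first reduced to the
#' asymmetric unit.
#'
#' @param rs a `reflection_set`.
#' @param d_min resolution limit in Angstrom.
#' @param mode "P1" (default) or "sg".
#' @return fraction in [0, 1].
#' @export
completeness <- function(rs, d_min, mode = c("P1", "sg")) {
  mode <- match.arg(mode)
  full <- enumerate_hkl(rs$cell, d_min)
  q_obs <- hkl_q(rs$hkl, rs$cell)
  obs <- rs$hkl[q_obs <= 1 / d_min + 1e-12, , drop = FALSE]
  if (mode == "P1") return(nrow(obs) / nrow(full))
  key_obs <- unique(hkl_key(asu_map(obs, rs$sg)$rep))
  key_full <- unique(hkl_key(asu_map(full, rs$sg)$rep))
  length(key_obs) / length(key_full)
}

#' Intensity-weighted phase residual against a reference
#'
#' Mean absolute wrapped phase difference (degrees) between a data set and a
#' reference over their shared reflections, weighted by the geometric mean of
#' the two intensities.
#'
#' @param rs a `reflection_set`.
#' @param ref reference `reflection_set` (e.g. noise-free structure factors).
#' @return residual in degrees.
#' @export
phase_residual_ref <- function(rs, ref) {
  sh <- rs_match(ref, rs)
  if (nrow(sh) == 0) stop("no shared reflections with the reference")
  w <- sqrt(ref$I[sh$ia] * rs$I[sh$ib])
  if (sum(w) <= 0) w <- rep(1, nrow(sh))
  d <- abs(wrap_deg(ref$phase[sh$ia] - rs$phase[sh$ib]))
  sum(w * d) / sum(w)
}

#' Intensity correlation against a reference
#'
#' Pearson correlation of log-intensities over shared reflections with
#' positive intensities.
#'
#' @param rs a `reflection_set`.
#' @param ref reference `reflection_set`.
#' @return correlation coefficient.
#' @export
intensity_cc <- function(rs, ref) {
  sh <- rs_match(ref, rs)
  ok <- ref$I[sh$ia] > 0 & rs$I[sh$ib] > 0
  sh <- sh[ok, , drop = FALSE]
  if (nrow(sh) < 3) stop("need at least 3 shared positive-intensity reflections")
  x <- log(ref$I[sh$ia]); y <- log(rs$I[sh$ib])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate intensity variance")
  stats::cor(x, y)
}

#' Real-space density map from a reflection set
#'
#' Expands the data over the space group and Friedel symmetry and computes a
#' unit-cell density map by Fourier synthesis from amplitudes `sqrt(I)` and
#' the stored phases (F(000) set to zero).
#'
#' @param rs a `reflection_set`.
#' @param grid_d resolution used to set the grid (spacing `grid_d / 3` per
#'   axis); defaults to the data resolution limit.
#' @param dims optional explicit grid dimensions (3 integers), overriding
#'   `grid_d`.
#' @return 3D numeric array of density values over the unit cell.
#' @export
density_map <- function(rs, grid_d = NULL, dims = NULL) {
  if (is.null(grid_d)) grid_d <- 1 / max(hkl_q(rs$hkl, rs$cell))
  if (is.null(dims))
    dims <- vapply(cell_lengths(rs$cell),
                   function(len) next_smooth(3 * len / grid_d), 1L)
  gr <- group_reduce(sym_prep(rs))
  sp <- skew_prep(gr$rep, gr$I, rs$sg, dims)
  skew_map_values(sp, gr$phi_rad)
}

#' Map correlation against a reference
#'
#' Pearson correlation between the density maps ([density_map()]) of a data
#' set and a reference, computed on a common grid (dimensions set by the
#' reference cell at the lower of the two resolution limits), so small cell
#' differences between the sets do not change the grid.
#'
#' @param rs a `reflection_set`.
#' @param ref reference `reflection_set` (same cell and space group).
#' @param grid_d optional common synthesis resolution.
#' @return correlation coefficient.
#' @export
map_cc <- function(rs, ref, grid_d = NULL) {
  if (is.null(grid_d))
    grid_d <- max(1 / max(hkl_q(rs$hkl, rs$cell)),
                  1 / max(hkl_q(ref$hkl, ref$cell)))
  dims <- vapply(cell_lengths(ref$cell),
                 function(len) next_smooth(3 * len / grid_d), 1L)
  stats::cor(as.vector(density_map(rs, dims = dims)),
             as.vector(density_map(ref, dims = dims)))
}
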