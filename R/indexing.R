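## Bragg-spot finding and lattice indexing of a Fourier volume.
##
## Indexing follows the 1D-FFT family of algorithms: candidate real-space
## basis directions are sampled on a hemisphere, the reciprocal-space spot
## positions are projected onto each direction, and the periodogram of the
## projected coordinates peaks at the real-cell repeat when the direction
## is parallel to a real basis vector.

#' Find Bragg spots in a Fourier volume
#'
#' Scans the intensity grid slice by slice along x, marking pixels brighter
#' than `mean + gain * sd` of their slice, merges contiguous bright pixels
#' across slices (26-connectivity), and filters the resulting spots by a
#' resolution window and pixel-count limits.
#'
#' @param fv a `fourier_volume`.
#' @param gain dispersion threshold in slice standard deviations (default 6).
#' @param d_limits resolution window in Angstrom `c(d_max, d_min)`; spots
#'   outside are dropped (default `c(Inf, 0)` keeps everything except the
#'   direct beam).
#' @param pixel_limits `c(min, max)` pixels per spot.
#' @param beam_radius voxels around the zero-frequency voxel to exclude.
#' @return data frame of spots: centroid voxel offsets from the grid center
#'   (`x`,`y`,`z`, intensity-weighted), total `intensity`, pixel count
#'   `n_pixels`, and resolution `d` (Angstrom).
#' @export
find_spots <- function(fv, gain = 6, d_limits = c(Inf, 0),
                       pixel_limits = c(3, 300), beam_radius = 3) {
  stopifnot(gain > 0)
  I <- fourier_intensity(fv)
  d <- dim(I)
  mask <- array(FALSE, d)
  for (ix in seq_len(d[1])) {
    sl <- I[ix, , ]
    mask[ix, , ] <- sl > mean(sl) + gain * stats::sd(sl)
  }
  lab <- array(cpp_label3d(as.vector(mask), d[1], d[2], d[3]), d)
  if (max(lab) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0), n_pixels = integer(0),
                      d = numeric(0)))
  sel <- which(lab > 0)
  idx <- arrayInd(sel, d) - 1L
  g <- lab[sel]
  w <- I[sel]
  cen <- rowsum(idx * w, g) / as.vector(rowsum(w, g))
  tot <- as.vector(rowsum(w, g))
  npx <- as.vector(rowsum(rep(1, length(g)), g))
  cen <- sweep(cen, 2, fv$center, "-")   # voxel offsets from the DC voxel
  qv <- sweep(cen, 2, fv$dq, "*")
  q <- sqrt(rowSums(qv^2))
  keep <- npx >= pixel_limits[1] & npx <= pixel_limits[2] &
    sqrt(rowSums(cen^2)) > beam_radius &
    q >= 1 / d_limits[1] & q <= ifelse(d_limits[2] > 0, 1 / d_limits[2], Inf)
  data.frame(x = cen[keep, 1], y = cen[keep, 2], z = cen[keep, 3],
             intensity = tot[keep], n_pixels = as.integer(npx[keep]),
             d = 1 / q[keep])
}

## roughly uniform hemisphere directions (Fibonacci lattice, z >= 0)
hemisphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere only
  r <- sqrt(1 - z^2)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Index a spot list
#'
#' Recovers a real-space basis from reciprocal-space spot positions by
#' periodogram scoring of hemisphere directions, selects the best
#' non-coplanar direction triplet, assigns Miller indices (the projection of
#' a reciprocal point onto a real basis vector is its index), and
#' least-squares refines the reciprocal basis against the assignments.
#'
#' @param spots data frame from [find_spots()].
#' @param dq reciprocal voxel sizes (inverse Angstrom per voxel, 3-vector)
#'   used to convert voxel offsets to physical coordinates.
#' @param period_range candidate real-space repeat range in Angstrom.
#' @param n_dirs hemisphere sampling density (default 4000, about 2 degrees).
#' @param n_candidates direction shortlist size for triplet selection.
#' @return list of class `indexing_solution`: `A` (3x3, reciprocal basis
#'   rows: `q = h %*% A` in inverse Angstrom), `cell` (a `unit_cell`), `hkl`
#'   (assigned indices), `residual` (mean fractional indexing residual) and
#'   `spots`.
#' @export
index_lattice <- function(spots, dq, period_range = c(10, 60), n_dirs = 1500,
                          n_candidates = 12, n_score = 150) {
  S <- cbind(spots$x * dq[1], spots$y * dq[2], spots$z * dq[3])
  if (nrow(S) < 6 || qr(S)$rank < 3) stop("degenerate lattice")
  ## direction scoring on the strongest spots only (cost control)
  Ssc <- S[order(spots$intensity, decreasing = TRUE)[
    seq_len(min(n_score, nrow(S)))], , drop = FALSE]
  df <- 0.15
  nf <- as.integer(ceiling(diff(period_range) / df)) + 1L
  D <- hemisphere_directions(n_dirs)
  sc <- cpp_dps_score(Ssc, D, period_range[1], df, nf)
  ## direction shortlist: greedy pick by score, enforcing angular separation
  ord <- order(sc$score, decreasing = TRUE)
  picked <- integer(0)
  for (j in ord) {
    if (length(picked) >= n_candidates) break
    if (all(abs(D[picked, , drop = FALSE] %*% D[j, ]) < cos(10 * pi / 180)))
      picked <- c(picked, j)
  }
  if (length(picked) < 3) stop("degenerate lattice")
  V <- D[picked, , drop = FALSE] * sc$f[picked]   # real-space basis candidates
  ## best non-coplanar triplet by summed score
  trip <- utils::combn(seq_along(picked), 3)
  best <- NULL; best_score <- -Inf
  for (t in seq_len(ncol(trip))) {
    M <- V[trip[, t], ]
    vol <- abs(det(M))
    if (vol < 0.05 * prod(sqrt(rowSums(M^2)))) next
    s <- sum(sc$score[picked[trip[, t]]])
    if (s > best_score) { best_score <- s; best <- M }
  }
  if (is.null(best)) stop("degenerate lattice")
  best <- lattice_reduce(best)
  ## bootstrap the assignment: index low-resolution spots first (tolerant of
  ## direction-grid error), refine the basis, then index everything
  q <- sqrt(rowSums(S^2))
  fit <- NULL
  for (sel in list(which(q <= stats::quantile(q, 0.3)), seq_len(nrow(S)))) {
    M <- if (is.null(fit)) best else t(solve(fit))  # real basis rows
    H <- round(S[sel, , drop = FALSE] %*% t(M))     # h_i = q . a_i
    H <- gcd_reduce_columns(H)
    if (qr(H)$rank < 3) stop("degenerate lattice")
    fit <- qr.solve(H, S[sel, , drop = FALSE])      # LS fit of q = h %*% A
  }
  A <- fit
  ## reduce the fitted real basis so the cell is comparable up to re-basis
  M <- lattice_reduce(t(solve(A)))
  A <- t(solve(M))
  frac <- S %*% solve(A)
  residual <- mean(abs(frac - round(frac)))
  H <- round(frac)
  structure(list(A = A, cell = cell_from_reciprocal(t(A)), hkl = H,
                 residual = residual, spots = spots, S = S),
            class = "indexing_solution")
}

## pairwise (Lagrange-style) reduction of a 3D basis given as matrix rows;
## also orders rows by length and fixes a right-handed, positive-axis gauge
lattice_reduce <- function(M) {
  repeat {
    changed <- FALSE
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      m <- round(sum(M[i, ] * M[j, ]) / sum(M[j, ]^2))
      if (m != 0) {
        M[i, ] <- M[i, ] - m * M[j, ]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M <- M[order(rowSums(M^2)), , drop = FALSE]
  for (i in 1:3) if (M[i, which.max(abs(M[i, ]))] < 0) M[i, ] <- -M[i, ]
  if (det(M) < 0) M[3, ] <- -M[3, ]
  M
}

## divide away a common integer factor per index column (harmonic guard:
## a doubled basis-vector length yields all-even indices on that axis)
gcd_reduce_columns <- function(H) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  for (i in 1:3) {
    v <- abs(H[, i])
    v <- v[v > 0]
    if (!length(v)) next
    g <- Reduce(gcd2, v)
    if (g > 1) H[, i] <- H[, i] / g
  }
  H
}

#' @export
print.indexing_solution <- function(x, ...) {
  cat(sprintf("indexing solution: %d spots, mean fractional residual %.4f\n",
              nrow(x$hkl), x$residual))
  print(x$cell)
  invisible(x)
}

## Kabsch rotation aligning rows of M_ref onto rows of M_est
## proper rotation R minimizing ||M_ref %*% R - M_est||_F (rows as vectors)
kabsch <- function(M_ref, M_est) {
  s <- svd(t(M_ref) %*% M_est)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Refine a cell under space-group constraints
#'
#' Projects the fitted cell onto the subspace allowed by the space group's
#' crystal system (monoclinic: alpha = gamma = 90; orthorhombic: all angles
#' 90; tetragonal: additionally a = b), then rebuilds the reciprocal basis in
#' the same orientation (least-squares rotation fit to the unconstrained
#' basis) and re-derives the indexing residual.
#'
#' @param sol an `indexing_solution`.
#' @param sg a `space_group` or symbol.
#' @param max_violation largest tolerated relative constraint violation
#'   (default 0.05); exceeding it suggests a wrong space group.
#' @return the refined `indexing_solution` (with `sg` attached).
#' @export
refine_cell_symmetry <- function(sol, sg, max_violation = 0.05) {
  sg <- space_group(sg)
  cl <- sol$cell
  system <- sol_crystal_system(sg$symbol)
  ang <- c(cl$alpha, cl$beta, cl$gamma)
  fix_ang <- switch(system,
                    triclinic = c(FALSE, FALSE, FALSE),
                    monoclinic = c(TRUE, FALSE, TRUE),
                    c(TRUE, TRUE, TRUE))
  if (any(abs(ang[fix_ang] - 90) / 90 > max_violation))
    stop("space-group constraint violation exceeds ",
         max_violation * 100, "%: check the space group")
  ang[fix_ang] <- 90
  len <- cell_lengths(cl)
  if (system == "tetragonal") {
    if (abs(len[1] - len[2]) / mean(len[1:2]) > max_violation)
      stop("space-group constraint violation exceeds ",
           max_violation * 100, "%: check the space group")
    len[1:2] <- mean(len[1:2])
  }
  cell_c <- unit_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3])
  ## rebuild the reciprocal basis with the constrained cell in the
  ## orientation closest to the fitted one
  A_ideal <- t(reciprocal_basis(cell_c))          # rows a*, b*, c*
  R <- kabsch(A_ideal, sol$A)
  A_new <- A_ideal %*% R
  frac <- sol$S %*% solve(A_new)
  out <- sol
  out$A <- A_new
  out$cell <- cell_c
  out$residual <- mean(abs(frac - round(frac)))
  out$sg <- sg
  out
}

sol_crystal_system <- function(symbol) {
  switch(symbol,
         P1 = "triclinic",
         P2 = , P21 = "monoclinic",
         P222 = , P212121 = "orthorhombic",
         P4 = , P41 = , P43 = , P41212 = , P43212 = "tetragonal",
         stop("unsupported space group symbol: ", symbol))
}
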