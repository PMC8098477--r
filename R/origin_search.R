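## Locating a crystallographic phase origin for a merged, P1-phased data set.
##
## Candidate origins on a fractional grid are scored by three metrics:
##  - the intensity-weighted phase residual among symmetry-equivalent
##    reflections (after transporting each observation to its orbit
##    representative),
##  - the intensity-weighted distance of centric phases to their allowed
##    (180-degree-spaced) values,
##  - the negated skew of the symmetry-averaged density map (protein maps are
##    positively skewed; random maps are Gaussian).
## Available metrics are normalized and summed with equal weight; the
## candidate with the lowest combined score is the origin.

## precompute the symmetry-orbit structure of an observed reflection list:
## each observation maps to its orbit representative with
## phi(rep) = sign * (phi_obs - 360 h_obs . t_op); under an origin shift u the
## estimate becomes psi - 2 pi f . u with psi in radians and f = sign * h_obs.
sym_prep <- function(rs) {
  sg <- rs$sg
  am <- asu_map(rs$hkl, sg)
  tmat <- t(vapply(sg$ops, function(op) op$t, numeric(3)))
  tt <- tmat[am$op, , drop = FALSE]
  psi <- am$sign * (rs$phase - 360 * rowSums(rs$hkl * tt))
  f <- rs$hkl * am$sign
  key <- hkl_key(am$rep)
  gid <- match(key, unique(key))
  ord <- order(gid)
  list(rep = am$rep[ord, , drop = FALSE], gid = gid[ord],
       psi = (psi * pi / 180)[ord], f = f[ord, , drop = FALSE],
       w = rs$I[ord], multi = any(duplicated(gid)))
}

#' Symmetry-consensus phase estimate for one reflection
#'
#' Transports every observed symmetry equivalent of `h` back to an estimate of
#' the phase of `h` (shifted to origin `u`) and returns the intensity-weighted
#' circular mean of the estimates.
#'
#' @param rs a `reflection_set`.
#' @param h Miller index 3-vector.
#' @param u fractional origin shift (default none).
#' @return circular mean phase estimate in degrees.
#' @export
symmetry_mean_phase <- function(rs, h, u = c(0, 0, 0)) {
  prep <- sym_prep(rs)
  rep_h <- asu_map(rbind(as.integer(h)), rs$sg)$rep[1, ]
  sel <- which(prep$rep[, 1] == rep_h[1] & prep$rep[, 2] == rep_h[2] &
               prep$rep[, 3] == rep_h[3])
  if (!length(sel)) stop("no observed symmetry equivalent of the reflection")
  est <- prep$psi[sel] * 180 / pi - 360 * as.vector(prep$f[sel, , drop = FALSE] %*% u)
  ## estimates refer to the orbit representative; transport back to h
  amh <- asu_map(rbind(as.integer(h)), rs$sg)
  top <- rs$sg$ops[[amh$op[1]]]$t
  mean_rep <- circ_mean_deg(est, prep$w[sel])
  ## phi(rep) = sign * (phi(h) - 360 h.t)  =>  phi(h) = sign*phi(rep) + 360 h.t
  wrap_deg(amh$sign[1] * mean_rep + 360 * sum(as.numeric(h) * top))
}

#' Symmetry phase residual of a reflection set at an origin
#'
#' Intensity-weighted mean absolute wrapped deviation between each
#' observation's transported phase estimate and its orbit's weighted circular
#' mean, over orbits with at least two observations. Returns NA (metric
#' uninformative) when no symmetry-related pairs are observed, e.g. in P1.
#'
#' @param rs a `reflection_set`.
#' @param u fractional origin shift.
#' @return residual in degrees, or NA.
#' @export
symmetry_phase_residual <- function(rs, u = c(0, 0, 0)) {
  prep <- sym_prep(rs)
  if (!prep$multi) return(NA_real_)
  cpp_sym_residual_at(prep$f, prep$psi, prep$w, prep$gid,
                      matrix(u, 1)) * 180 / pi
}

#' Centric phase residual at an origin
#'
#' Intensity-weighted mean wrapped distance (modulo 180 degrees) of the
#' shifted centric phases to their nearest allowed value. Returns NA when the
#' data contain no centric reflections.
#'
#' @param rs a `reflection_set`.
#' @param u fractional origin shift.
#' @return residual in degrees, or NA.
#' @export
centric_residual <- function(rs, u = c(0, 0, 0)) {
  ci <- centric_info(rs$hkl, rs$sg)
  sel <- which(ci$centric)
  if (!length(sel)) return(NA_real_)
  delta <- (rs$phase[sel] - ci$theta[sel]) * pi / 180
  cpp_centric_residual_at(rs$hkl[sel, , drop = FALSE], delta, rs$I[sel],
                          matrix(u, 1)) * 180 / pi
}

## precompute the symmetry expansion used for map synthesis: orbit
## representatives expanded over all operators and Friedel mates, with linear
## positions in the synthesis grid and phase-transport constants.
skew_prep <- function(rep_hkl, I_rep, sg, dims) {
  nop <- length(sg$ops)
  n <- nrow(rep_hkl)
  blocks <- vector("list", 2 * nop)
  for (s in seq_len(nop)) {
    he <- rep_hkl %*% sg$ops[[s]]$R
    dph <- -360 * as.vector(rep_hkl %*% sg$ops[[s]]$t)
    blocks[[s]] <- list(h = he, sign = 1, dph = dph)
    blocks[[nop + s]] <- list(h = -he, sign = -1, dph = -dph)
  }
  h_all <- do.call(rbind, lapply(blocks, `[[`, "h"))
  sgn <- rep(vapply(blocks, `[[`, numeric(1), "sign"), each = n)
  dph <- unlist(lapply(blocks, `[[`, "dph"))
  gidx <- rep(seq_len(n), 2 * nop)
  idx <- sweep(h_all, 2, dims, "%%")
  lin <- 1 + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  amp <- sqrt(pmax(I_rep, 0))[gidx]
  list(lin = lin, sign = sgn, dph = dph * pi / 180, gidx = gidx, amp = amp,
       dims = dims)
}

## density map values from per-representative phases (radians)
skew_map_values <- function(sp, phi_rep_rad) {
  ph <- sp$sign * phi_rep_rad[sp$gidx] + sp$dph
  z <- sp$amp * exp(1i * ph)
  agg <- rowsum(cbind(Re(z), Im(z), 1), sp$lin)
  G <- array(0i, sp$dims)
  pos <- as.integer(rownames(agg))
  G[pos] <- (agg[, 1] + 1i * agg[, 2]) / agg[, 3]
  G[1, 1, 1] <- 0
  Re(stats::fft(G, inverse = TRUE))
}

density_skew <- function(m) {
  m <- m - mean(m)
  s <- sqrt(mean(m^2))
  if (s == 0) return(0)
  mean(m^3) / s^3
}

#' Negative skew of the symmetry-averaged density map
#'
#' Shifts the phases to origin `u`, reduces to the asymmetric unit, expands
#' back over the space group and Friedel symmetry, synthesizes a unit-cell
#' density map from (I^1/2, phase) and returns the negated skew of the
#' density values. Protein-like maps on a correct origin give a clearly
#' negative value; misplaced origins wash out the symmetry-averaged
#' amplitudes and push the skew towards zero.
#'
#' @param rs a `reflection_set`.
#' @param u fractional origin shift.
#' @param grid_d resolution used to set the synthesis grid (spacing
#'   `grid_d / 3` per axis); defaults to the data resolution limit.
#' @return negated skew (unitless).
#' @export
map_skew <- function(rs, u = c(0, 0, 0), grid_d = NULL) {
  if (n_reflections(rs) < 10) stop("need at least 10 reflections for a map")
  if (is.null(grid_d)) grid_d <- 1 / max(hkl_q(rs$hkl, rs$cell))
  dims <- vapply(cell_lengths(rs$cell),
                 function(len) next_smooth(3 * len / grid_d), 1L)
  prep <- sym_prep(phase_shift(rs, u))
  gr <- group_reduce(prep)
  sp <- skew_prep(gr$rep, gr$I, rs$sg, dims)
  -density_skew(skew_map_values(sp, gr$phi_rad))
}

## weighted circular mean phase and mean intensity per orbit
group_reduce <- function(prep) {
  z <- prep$w * exp(1i * prep$psi)
  agg <- rowsum(cbind(Re(z), Im(z), prep$w, 1), prep$gid)
  first <- !duplicated(prep$gid)
  list(rep = prep$rep[first, , drop = FALSE],
       phi_rad = atan2(agg[, 2], agg[, 1]),
       I = agg[, 3] / agg[, 4],
       mult = agg[, 4])
}

#' Locate a crystallographic phase origin
#'
#' Scans a fractional grid of candidate origins (spacing at least as fine as
#' `interval` Angstrom per axis) and scores each candidate by the available
#' metrics (symmetry phase residual, centric residual, negated map skew),
#' normalized across candidates and summed with equal weight.
#'
#' The default "hierarchical" method scores the full grid with an exact FFT
#' phase-coherence figure (one inverse FFT), evaluates the exact residual
#' metrics on the `top_k` most coherent candidates and the map skew on the
#' best `top_skew` of those, then combines z-scores over that shortlist. The
#' "exhaustive" method evaluates all metrics at every node (practical only
#' for coarse grids) and is the reference implementation.
#'
#' @param rs a merged `reflection_set` (non-P1 space group).
#' @param interval grid sampling interval in Angstrom (default 0.2).
#' @param method "hierarchical" (default) or "exhaustive".
#' @param normalize "zscore" (default) or "minmax" metric normalization.
#' @param top_k,top_skew shortlist sizes for the hierarchical method.
#' @param grid_d map-synthesis resolution passed to [map_skew()].
#' @return list with `u` (fractional origin shift), `scores` (data frame of
#'   evaluated candidates and their metrics), and `note`.
#' @export
find_crystallographic_origin <- function(rs, interval = 0.2,
                                         method = c("hierarchical",
                                                    "exhaustive"),
                                         normalize = c("zscore", "minmax"),
                                         top_k = 1024, top_skew = 64,
                                         grid_d = NULL) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  if (rs$sg$symbol == "P1")
    return(list(u = c(0, 0, 0), scores = NULL,
                note = "P1: every origin is crystallographic"))
  dims <- origin_grid_dims(rs$cell, interval)
  prep <- sym_prep(rs)
  ci <- centric_info(rs$hkl, rs$sg)
  csel <- which(ci$centric)
  have_sym <- prep$multi
  have_cen <- length(csel) > 0
  if (!have_sym && !have_cen)
    stop("no symmetry-related pairs and no centric reflections; origin not determinable")
  cdelta <- (rs$phase[csel] - ci$theta[csel]) * pi / 180
  chkl <- rs$hkl[csel, , drop = FALSE]
  cw <- rs$I[csel]

  if (method == "exhaustive") {
    idx <- as.matrix(expand.grid(a = 0:(dims[1] - 1), b = 0:(dims[2] - 1),
                                 c = 0:(dims[3] - 1)))
    U <- sweep(idx, 2, dims, "/")
  } else {
    ## one coefficient list for both coherence terms, one grid accumulation
    ms <- NULL; zs <- NULL
    if (have_sym) {
      sc <- sym_coherence_terms(prep)
      ms <- sc$m; zs <- sc$z / sc$norm
    }
    if (have_cen) {
      ms <- rbind(ms, -2 * chkl)
      zs <- c(zs, cw * exp(2i * cdelta) / sum(cw))
    }
    top <- coherence_topk(accumulate_coef(ms, zs, dims), top_k)
    U <- top$U
  }
  sym <- if (have_sym)
    cpp_sym_residual_at(prep$f, prep$psi, prep$w, prep$gid, U) * 180 / pi
  else rep(NA_real_, nrow(U))
  cen <- if (have_cen)
    cpp_centric_residual_at(chkl, cdelta, cw, U) * 180 / pi
  else rep(NA_real_, nrow(U))

  norm_fun <- function(x) {
    if (all(is.na(x))) return(x)
    if (normalize == "zscore") {
      s <- stats::sd(x)
      if (s == 0) return(x * 0)
      (x - mean(x)) / s
    } else {
      r <- range(x)
      if (diff(r) == 0) return(x * 0)
      (x - r[1]) / diff(r)
    }
  }
  phase_comb <- rowMeans(cbind(norm_fun(sym), norm_fun(cen)), na.rm = TRUE)

  if (method == "exhaustive") {
    ksel <- seq_len(nrow(U))
  } else {
    ksel <- order(phase_comb)[seq_len(min(top_skew, nrow(U)))]
  }
  skew <- rep(NA_real_, nrow(U))
  if (n_reflections(rs) >= 10) {
    if (is.null(grid_d)) grid_d <- 1 / max(hkl_q(rs$hkl, rs$cell))
    mdims <- vapply(cell_lengths(rs$cell),
                    function(len) next_smooth(3 * len / grid_d), 1L)
    for (k in ksel) {
      pk <- prep
      pk$psi <- prep$psi - 2 * pi * as.vector(prep$f %*% U[k, ])
      gr <- group_reduce(pk)
      if (k == ksel[1]) sp <- skew_prep(gr$rep, gr$I, rs$sg, mdims)
      skew[k] <- -density_skew(skew_map_values(sp, gr$phi_rad))
    }
  }
  sub <- ksel
  comb <- rowMeans(cbind(norm_fun(sym[sub]), norm_fun(cen[sub]),
                         norm_fun(skew[sub])), na.rm = TRUE)
  u <- pick_min_candidate(U[sub, , drop = FALSE], comb, eps = 1e-9)
  scores <- data.frame(ua = U[sub, 1], ub = U[sub, 2], uc = U[sub, 3],
                       sym_residual = sym[sub], centric_residual = cen[sub],
                       neg_skew = skew[sub], combined = comb)
  list(u = u, scores = scores[order(scores$combined), ], note = NULL)
}

## Fourier coefficients of the symmetry phase-coherence score
## sum_g |Z_g(u)|^2 (orbit resultants), plus its normalization constant.
sym_coherence_terms <- function(prep) {
  keep <- prep$gid %in% prep$gid[duplicated(prep$gid)]
  f <- prep$f[keep, , drop = FALSE]
  psi <- prep$psi[keep]
  w <- prep$w[keep]
  gid <- prep$gid[keep]
  parts_m <- list(); parts_z <- list()
  for (g in unique(gid)) {
    sel <- which(gid == g)
    k <- length(sel)
    a <- rep(sel, each = k); b <- rep(sel, k)
    parts_m[[length(parts_m) + 1]] <-
      -(f[a, , drop = FALSE] - f[b, , drop = FALSE])
    parts_z[[length(parts_z) + 1]] <- w[a] * w[b] * exp(1i * (psi[a] - psi[b]))
  }
  sw <- rowsum(w, gid)
  list(m = do.call(rbind, parts_m), z = unlist(parts_z), norm = sum(sw^2))
}

#' Reduce a reflection set to the asymmetric unit
#'
#' Optionally shifts the phases to origin `u`, maps every reflection to its
#' canonical asymmetric-unit representative (transporting the phase through
#' the symmetry operator and Friedel relation), and combines multiple
#' observations of the same representative: intensity-weighted circular mean
#' phase, mean intensity, summed multiplicity.
#'
#' @param rs a `reflection_set`.
#' @param u optional fractional origin shift applied first.
#' @return a `reflection_set` of unique asymmetric-unit reflections.
#' @export
reduce_to_asu <- function(rs, u = NULL) {
  if (!is.null(u)) rs <- phase_shift(rs, u)
  prep <- sym_prep(rs)
  gr <- group_reduce(prep)
  key <- hkl_key(asu_map(rs$hkl, rs$sg)$rep)
  gid <- match(key, unique(key))
  mult <- as.vector(rowsum(rs$mult, gid))  # rows ordered by gid, like gr
  reflection_set(gr$rep, gr$I, gr$phi_rad * 180 / pi, rs$cell, rs$sg,
                 mult = mult)
}
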