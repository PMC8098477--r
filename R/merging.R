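## Phase-origin alignment and merging of reflection sets.
##
## Shifting the real-space origin by the fractional vector u changes every
## phase by -360 * (h . u); intensities are unaffected. Aligning two data
## sets means finding the u that minimizes the intensity-weighted mean
## absolute wrapped residual between reference phases and shifted phases over
## the shared reflections, searched on a fractional grid sampling the cell at
## a fixed interval (Angstrom) per axis.

#' Shift the phase origin of a reflection set
#'
#' Applies the translation theorem: `phase'(h) = wrap(phase(h) - 360 h.u)`.
#'
#' @param rs a `reflection_set`.
#' @param u fractional unit-cell 3-vector.
#' @return the shifted `reflection_set` (intensities unchanged).
#' @export
phase_shift <- function(rs, u) {
  stopifnot(length(u) == 3)
  rs$phase <- wrap_deg(rs$phase - 360 * as.vector(rs$hkl %*% u))
  rs
}

#' Origin-search grid dimensions
#'
#' Number of fractional grid nodes per axis used by the origin searches: the
#' smallest 5-smooth integer at least `cell_length / interval`, so the spacing
#' is at least as fine as requested while keeping FFT sizes fast.
#'
#' @param cell a `unit_cell`.
#' @param interval sampling interval in Angstrom.
#' @return integer 3-vector of grid dimensions.
#' @export
origin_grid_dims <- function(cell, interval) {
  vapply(cell_lengths(cell), function(len) next_smooth(len / interval), 1L)
}

grid_u <- function(idx0, dims) idx0 / dims  # 0-based indices -> fractional

## shortlist of candidate origins by FFT phase coherence.
## coef: complex array of Fourier coefficients such that
## coherence(u) = Re sum_m coef[m] exp(+2 pi i m . u) on the fractional grid.
coherence_topk <- function(coef, k) {
  coh <- Re(stats::fft(coef, inverse = TRUE))
  k <- min(k, length(coh))
  ## partial selection: full order() of multi-million grids is the bottleneck
  thr <- sort(coh, partial = length(coh) - k + 1)[length(coh) - k + 1]
  cand <- which(coh >= thr)
  ord <- cand[order(coh[cand], decreasing = TRUE)][seq_len(k)]
  dims <- dim(coef)
  idx <- arrayInd(ord, dims) - 1L
  list(U = sweep(idx, 2, dims, "/"), coherence = coh[ord], idx = idx)
}

## accumulate w * exp(i psi) at frequency index (m mod dims) into a complex
## array (for inverse-FFT coherence evaluation)
accumulate_coef <- function(m, z, dims) {
  idx <- sweep(m, 2, dims, "%%")
  lin <- 1 + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  coef <- array(0i, dims)
  agg <- rowsum(cbind(Re(z), Im(z)), lin)
  pos <- as.integer(rownames(agg))
  coef[pos] <- agg[, 1] + 1i * agg[, 2]
  coef
}

#' Align the phase origin of one reflection set to a reference
#'
#' Finds the fractional shift u minimizing the intensity-weighted mean
#' absolute wrapped phase residual between the reference and the shifted
#' second set over their shared reflections. The exhaustive mode scans every
#' node of the fractional grid; the FFT mode scores the full grid by phase
#' coherence (a single inverse FFT), then evaluates the exact residual on the
#' top candidates. Both return the exact residual at the selected shift.
#'
#' @param ref reference `reflection_set`.
#' @param other `reflection_set` to be shifted onto the reference origin.
#' @param interval grid sampling interval in Angstrom (default 0.2).
#' @param weight how to weight shared reflections: geometric mean of the two
#'   intensities (default) or arithmetic mean.
#' @param method "fft" (default, shortlist + exact rescore), or "exhaustive".
#' @param top_k shortlist size for the FFT mode.
#' @return list with `u` (fractional shift), `residual` (degrees), `n_shared`,
#'   and `shifted` (the aligned copy of `other`).
#' @export
origin_alignment <- function(ref, other, interval = 0.2,
                             weight = c("geometric", "arithmetic"),
                             method = c("fft", "exhaustive"),
                             top_k = 4096) {
  weight <- match.arg(weight)
  method <- match.arg(method)
  sh <- rs_match(ref, other)
  if (nrow(sh) == 0) stop("disjoint reflection sets: no shared reflections")
  if (nrow(sh) < 3)
    warning("fewer than 3 shared reflections; origin shift ill-determined")
  hkl <- ref$hkl[sh$ia, , drop = FALSE]
  if (nrow(hkl) >= 3 && qr(matrix(as.numeric(hkl), ncol = 3))$rank < 3)
    warning("shared reflections coplanar; shift ill-determined along one axis")
  w <- if (weight == "geometric") sqrt(ref$I[sh$ia] * other$I[sh$ib])
       else 0.5 * (ref$I[sh$ia] + other$I[sh$ib])
  if (sum(w) <= 0) w <- rep(1, nrow(sh))
  dphi <- wrap_deg(ref$phase[sh$ia] - other$phase[sh$ib]) * pi / 180
  dims <- origin_grid_dims(ref$cell, interval)
  if (method == "exhaustive") {
    res <- cpp_align_residual_grid(hkl, dphi, w, dims[1], dims[2], dims[3])
    u <- grid_u(res$idx, dims)
    resid <- res$residual * 180 / pi
  } else {
    ## coherence(u) = sum w cos(dphi + 2 pi h.u): coefficients at +h
    coef <- accumulate_coef(hkl, w * exp(1i * dphi), dims)
    top <- coherence_topk(coef, top_k)
    rr <- cpp_align_residual_at(hkl, dphi, w, top$U)
    u <- pick_min_candidate(top$U, rr)
    resid <- min(rr) * 180 / pi
  }
  list(u = u, residual = resid, n_shared = nrow(sh),
       shifted = phase_shift(other, u))
}

## argmin with ties broken by smaller minimal-image norm, then lexicographic
pick_min_candidate <- function(U, values, eps = 1e-12) {
  tie <- which(values <= min(values) + eps)
  if (length(tie) > 1) {
    d <- U[tie, , drop = FALSE]
    d <- d - round(d)
    n2 <- rowSums(d^2)
    tie <- tie[order(n2, U[tie, 1], U[tie, 2], U[tie, 3])]
  }
  as.vector(U[tie[1], ])
}

#' Merge error between fractional origin shifts
#'
#' Minimal-image (per-axis modulo 1, mapped to [-0.5, 0.5]) Euclidean distance
#' between an estimated and a true fractional shift.
#'
#' @param u_est,u_true fractional 3-vectors.
#' @return numeric scalar in [0, sqrt(0.75)].
#' @export
merge_error <- function(u_est, u_true) {
  d <- (u_est - u_true) - round(u_est - u_true)
  sqrt(sum(d^2))
}

#' Scale one reflection set's intensities to a reference
#'
#' Least-squares fit of `log(I_other / I_ref) = b + m q - q^2 sigma^2 / 2`
#' over shared reflections with positive intensities (the quadratic term is a
#' Debye-Waller factor; logarithmic residuals stabilize the fit). The second
#' set is rescaled by the inverse of the fitted model.
#'
#' @param ref reference `reflection_set`.
#' @param other `reflection_set` to rescale.
#' @return list with `params` (b, m, sigma and the raw quadratic coefficient)
#'   and `scaled` (the rescaled copy of `other`).
#' @export
scale_intensities <- function(ref, other) {
  sh <- rs_match(ref, other)
  ok <- ref$I[sh$ia] > 0 & other$I[sh$ib] > 0
  sh <- sh[ok, , drop = FALSE]
  if (nrow(sh) < 5) stop("need at least 5 shared positive-intensity reflections")
  q <- hkl_q(ref$hkl[sh$ia, , drop = FALSE], ref$cell)
  y <- log(other$I[sh$ib]) - log(ref$I[sh$ia])
  X <- cbind(1, q, q^2)
  cf <- stats::lm.fit(X, y)$coefficients
  sigma <- sqrt(max(0, -2 * cf[3]))
  q_all <- hkl_q(other$hkl, other$cell)
  other$I <- other$I * exp(-(cf[1] + cf[2] * q_all + cf[3] * q_all^2))
  list(params = list(b = unname(cf[1]), m = unname(cf[2]),
                     sigma = unname(sigma), c2 = unname(cf[3])),
       scaled = other)
}

#' Merge reflection sets onto a common phase origin
#'
#' Greedy merging: the first set is the reference; at each step the unmerged
#' set sharing the most reflections with the current reference is aligned
#' ([origin_alignment()]), rescaled ([scale_intensities()]) and combined. The
#' merged phase of each reflection is the intensity-weighted circular mean
#' over its observations, the merged intensity the plain mean, and the
#' multiplicity the observation count. Everything is done in P1: symmetry
#' relations are not used until a crystallographic origin is sought.
#'
#' @param sets list of `reflection_set` objects (>= 2).
#' @param interval alignment grid interval in Angstrom.
#' @param ... further arguments passed to [origin_alignment()].
#' @return list with `merged` (a `reflection_set`), `shifts` (per-step
#'   fractional shifts), `residuals` (per-step alignment residuals, degrees)
#'   and `order` (indices of `sets` in merge order).
#' @export
merge_datasets <- function(sets, interval = 0.2, ...) {
  stopifnot(length(sets) >= 2)
  ref <- sets[[1]]
  acc <- list(key = hkl_key(ref$hkl), hkl = ref$hkl,
              z = ref$I * exp(1i * ref$phase * pi / 180),
              sumI = ref$I, n = rep(1, n_reflections(ref)))
  remaining <- seq_along(sets)[-1]
  shifts <- list(); residuals <- numeric(0); order <- 1L
  current_ref <- ref
  while (length(remaining)) {
    nshared <- vapply(remaining, function(j)
      nrow(rs_match(current_ref, sets[[j]])), 1L)
    if (all(nshared == 0))
      stop("reflection set(s) ", paste(remaining, collapse = ", "),
           " share no reflections with the merged reference")
    j <- remaining[which.max(nshared)]
    al <- origin_alignment(current_ref, sets[[j]], interval = interval, ...)
    sc <- tryCatch(scale_intensities(current_ref, al$shifted)$scaled,
                   error = function(e) al$shifted)
    acc <- merge_accumulate(acc, sc)
    shifts[[length(shifts) + 1]] <- al$u
    residuals <- c(residuals, al$residual)
    order <- c(order, j)
    remaining <- setdiff(remaining, j)
    current_ref <- acc_to_set(acc, ref$cell, ref$sg)
  }
  list(merged = current_ref, shifts = shifts, residuals = residuals,
       order = order)
}

merge_accumulate <- function(acc, rs) {
  key <- hkl_key(rs$hkl)
  pos <- match(key, acc$key)
  new <- is.na(pos)
  old <- which(!new)
  if (length(old)) {
    p <- pos[old]
    acc$z[p] <- acc$z[p] + rs$I[old] * exp(1i * rs$phase[old] * pi / 180)
    acc$sumI[p] <- acc$sumI[p] + rs$I[old]
    acc$n[p] <- acc$n[p] + 1
  }
  if (any(new)) {
    acc$key <- c(acc$key, key[new])
    acc$hkl <- rbind(acc$hkl, rs$hkl[new, , drop = FALSE])
    acc$z <- c(acc$z, rs$I[new] * exp(1i * rs$phase[new] * pi / 180))
    acc$sumI <- c(acc$sumI, rs$I[new])
    acc$n <- c(acc$n, rep(1, sum(new)))
  }
  acc
}

acc_to_set <- function(acc, cell, sg) {
  reflection_set(acc$hkl, acc$sumI / acc$n, Arg(acc$z) * 180 / pi, cell, sg,
                 mult = acc$n)
}
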