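## Predicting Bragg positions from an indexing solution and extracting
## per-reflection intensity and phase from a Fourier volume.

#' Extraction configuration
#'
#' @param radius spherical subvolume radius in reciprocal voxels (default 7).
#' @param peak_sigma peak assignment threshold in subvolume standard
#'   deviations above the mean (default 4).
#' @param background_sigma masking threshold for the background estimate
#'   (default 2); must be below `peak_sigma`.
#' @param centroid_tol largest accepted centroid-to-prediction distance in
#'   voxels (default 2).
#' @param phase_std_max largest accepted intensity-weighted circular phase
#'   standard deviation in degrees (default 15).
#' @param d_min resolution limit in Angstrom.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(radius = 7, peak_sigma = 4,
                              background_sigma = 2, centroid_tol = 2,
                              phase_std_max = 15, d_min = 3.3) {
  stopifnot(radius > 0, peak_sigma > background_sigma, background_sigma > 0,
            centroid_tol > 0, phase_std_max > 0, d_min > 0)
  structure(list(radius = radius, peak_sigma = peak_sigma,
                 background_sigma = background_sigma,
                 centroid_tol = centroid_tol, phase_std_max = phase_std_max,
                 d_min = d_min),
            class = "extraction_config")
}

#' Predict Bragg peak positions
#'
#' Enumerates all Friedel-unique reflections of the solution's cell to
#' `d_min`, maps them to voxel coordinates through the indexing matrix, and
#' flags reflections in the missing wedge (reciprocal-space azimuth about
#' the tilt axis outside the tilt range). The direct beam (0,0,0) is
#' excluded.
#'
#' @param sol an `indexing_solution` (see [index_lattice()]).
#' @param dq reciprocal voxel sizes in inverse Angstrom (3-vector).
#' @param d_min resolution limit in Angstrom.
#' @param tilt_range half-range of the tilt series in degrees (default 60).
#' @return data frame with `h`,`k`,`l`, predicted voxel offsets `x`,`y`,`z`
#'   (from the grid center), resolution `d`, and `in_wedge`.
#' @export
predict_peaks <- function(sol, dq, d_min, tilt_range = 60) {
  hkl <- enumerate_hkl(sol$cell, d_min)
  Sq <- hkl %*% sol$A                      # physical reciprocal coords
  vox <- sweep(Sq, 2, dq, "/")
  theta <- wrap_half_deg(atan2(-Sq[, 3], Sq[, 2]) * 180 / pi)
  data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
             x = vox[, 1], y = vox[, 2], z = vox[, 3],
             d = 1 / sqrt(rowSums(Sq^2)),
             in_wedge = abs(theta) > tilt_range)
}

#' Extract one Bragg peak
#'
#' Applies the extraction heuristic to the spherical subvolume of
#' `cfg$radius` voxels around the predicted position: (1) pixels brighter
#' than `mean + peak_sigma * sd` of the subvolume are peak candidates;
#' (2) the contiguous candidate set whose centroid is nearest the prediction
#' is kept; (3) the observation is rejected ("partial") if that centroid is
#' further than `centroid_tol` voxels from the prediction; (4) the peak plus
#' any contiguous pixels above `mean + background_sigma * sd` are masked and
#' the background under the peak is estimated by interpolation from the
#' nearest unmasked pixels along each axis, then subtracted; (5) phase
#' outlier pixels are dropped one at a time (largest intensity-weighted
#' deviation first, ties to the weaker pixel) until the intensity-weighted
#' circular phase standard deviation is at most `phase_std_max`;
#' (6) intensity is the sum of background-subtracted pixel intensities and
#' phase the intensity-weighted circular mean.
#'
#' @param fv a `fourier_volume`.
#' @param h Miller index 3-vector (bookkeeping only).
#' @param pred predicted voxel offset from the grid center (3-vector, may be
#'   fractional).
#' @param cfg an `extraction_config`.
#' @return list with `h`, `accepted`, `reason` (NA when accepted),
#'   `intensity`, `phase` (degrees), `phase_std`, `centroid` (voxel offset),
#'   `n_pixels`.
#' @export
extract_peak <- function(fv, h, pred, cfg = extraction_config()) {
  d <- dim(fv$F)
  ctr0 <- pred + fv$center                 # 0-based voxel coords
  lo <- floor(ctr0) - cfg$radius
  hi <- floor(ctr0) + cfg$radius + 1
  rej <- function(reason) list(h = h, accepted = FALSE, reason = reason,
                               intensity = NA_real_, phase = NA_real_,
                               phase_std = NA_real_, centroid = rep(NA_real_, 3),
                               n_pixels = 0L)
  if (any(lo < 0) || any(hi > d - 1)) return(rej("edge"))
  ix <- (lo[1]:hi[1]) + 1L; iy <- (lo[2]:hi[2]) + 1L; iz <- (lo[3]:hi[3]) + 1L
  Isub <- fourier_intensity(fv)[ix, iy, iz]
  Psub <- fourier_phase(fv)[ix, iy, iz]
  sd3 <- dim(Isub)
  ## spherical footprint
  ax <- lo[1]:hi[1]; ay <- lo[2]:hi[2]; az <- lo[3]:hi[3]
  rr <- outer(outer((ax - ctr0[1])^2, (ay - ctr0[2])^2, "+"),
              (az - ctr0[3])^2, "+")
  inside <- rr <= cfg$radius^2
  ## background statistics by sigma clipping, so the peak itself does not
  ## inflate the thresholds
  bgpix <- Isub[inside]
  repeat {
    mu <- mean(bgpix); sg <- stats::sd(bgpix)
    keep_bg <- bgpix <= mu + cfg$background_sigma * sg
    if (all(keep_bg) || sum(keep_bg) < 8) break
    bgpix <- bgpix[keep_bg]
  }
  peak_mask <- inside & Isub > mu + cfg$peak_sigma * sg
  if (!any(peak_mask)) return(rej("no_peak"))
  lab <- array(cpp_label3d(as.vector(peak_mask), sd3[1], sd3[2], sd3[3]), sd3)
  ## contiguous set with centroid nearest the prediction
  cand <- seq_len(max(lab))
  cdist <- vapply(cand, function(g) {
    sel <- which(lab == g)
    id <- arrayInd(sel, sd3)
    w <- Isub[sel]
    cen <- colSums(id * w) / sum(w) - 1 + lo
    sqrt(sum((cen - ctr0)^2))
  }, numeric(1))
  g <- cand[which.min(cdist)]
  if (cdist[g] > cfg$centroid_tol) return(rej("partial"))
  sel <- which(lab == g)
  ## background mask: the peak set plus contiguous pixels above the lower
  ## threshold
  bg_mask <- inside & Isub > mu + cfg$background_sigma * sg
  lab2 <- array(cpp_label3d(as.vector(bg_mask), sd3[1], sd3[2], sd3[3]), sd3)
  mask <- lab2 == lab2[sel[1]] & lab2 > 0
  ## the observation is the whole contiguous above-background set containing
  ## the peak; background under it comes from the nearest unmasked pixels
  sel <- which(mask)
  bg <- estimate_background(Isub, mask, sel)
  ## iterative phase-outlier removal
  w <- pmax(Isub[sel] - bg[sel], 0)
  ph <- Psub[sel]
  keep <- seq_along(sel)
  n0 <- length(keep)
  repeat {
    if (length(keep) < 2) return(rej("phase_incoherent"))
    st <- weighted_phase_stats(ph[keep], w[keep])
    if (st$sd <= cfg$phase_std_max) break
    dev <- abs(wrap_deg(ph[keep] - st$mean)) * w[keep]
    worst <- which(dev == max(dev))
    if (length(worst) > 1) worst <- worst[which.min(w[keep][worst])]
    keep <- keep[-worst]
  }
  ## a genuine peak loses at most a few outlier pixels; if coherence was
  ## only reached by discarding most of the peak, the phases are noise
  if (length(keep) < ceiling(n0 / 2)) return(rej("phase_incoherent"))
  sel <- sel[keep]
  w <- w[keep]
  st <- weighted_phase_stats(Psub[sel], w)
  id <- arrayInd(sel, sd3)
  centroid <- colSums(id * Isub[sel]) / sum(Isub[sel]) - 1 + lo - fv$center
  ## the value-threshold mask excludes the Gaussian tail below the background
  ## threshold, which biases the sum low for weak peaks; rescale by the
  ## retained mass fraction of an isotropic Gaussian truncated at that level
  ## (the radius where the peak falls to the threshold is sqrt(2 log(A/tau))
  ## sigma, and the enclosed mass is the chi-squared_3 CDF at its square)
  A <- max(w)
  tau <- cfg$background_sigma * sg
  frac <- if (A > tau) max(stats::pchisq(2 * log(A / tau), df = 3), 0.2) else 1
  list(h = h, accepted = TRUE, reason = NA_character_,
       intensity = sum(w) / frac, phase = st$mean, phase_std = st$sd,
       centroid = centroid, n_pixels = length(sel))
}

## background under masked pixels: for each masked pixel, average the first
## unmasked neighbour found along each of the 6 axis directions; pixels whose
## rays all leave the subvolume fall back to the unmasked subvolume mean
estimate_background <- function(Isub, mask, sel) {
  d <- dim(Isub)
  bg <- array(0, d)
  fallback <- mean(Isub[!mask])
  for (s in sel) {
    id <- arrayInd(s, d)
    vals <- numeric(0)
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      p <- id
      repeat {
        p[axis] <- p[axis] + dir
        if (p[axis] < 1 || p[axis] > d[axis]) break
        if (!mask[p[1], p[2], p[3]]) {
          vals <- c(vals, Isub[p[1], p[2], p[3]])
          break
        }
      }
    }
    bg[s] <- if (length(vals)) mean(vals) else fallback
  }
  bg
}

#' Collect accepted peak observations into a reflection set
#'
#' Tabulates accepted observations; Friedel mates are mapped to the
#' positive-hemisphere convention first (conjugating the phase). True
#' duplicate indices (which should not occur within one tomogram) are
#' averaged with a warning. Tilt angles are carried per reflection for the
#' angular-spread diagnostics.
#'
#' @param obs list of observations from [extract_peak()].
#' @param cell a `unit_cell`.
#' @param sg a `space_group` or symbol.
#' @param tilt optional tilt angle in degrees per observation.
#' @return a `reflection_set` of the accepted observations.
#' @export
collect_reflections <- function(obs, cell, sg, tilt = NULL) {
  acc <- Filter(function(o) isTRUE(o$accepted), obs)
  if (is.null(tilt)) tilt <- rep(NA_real_, length(obs))
  tilt <- tilt[vapply(obs, function(o) isTRUE(o$accepted), logical(1))]
  if (!length(acc))
    return(reflection_set(matrix(integer(0), 0, 3), numeric(0), numeric(0),
                          cell, sg))
  hkl <- t(vapply(acc, function(o) as.integer(o$h), integer(3)))
  I <- vapply(acc, function(o) o$intensity, numeric(1))
  ph <- vapply(acc, function(o) o$phase, numeric(1))
  ## fold everything into the positive hemisphere (Friedel: phi(-h) = -phi(h))
  neg <- !(hkl[, 3] > 0 | (hkl[, 3] == 0 & hkl[, 2] > 0) |
           (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0))
  hkl[neg, ] <- -hkl[neg, , drop = FALSE]
  ph[neg] <- -ph[neg]
  key <- hkl_key(hkl)
  if (anyDuplicated(key)) {
    warning("duplicate Miller indices averaged")
    gid <- match(key, unique(key))
    z <- I * exp(1i * ph * pi / 180)
    agg <- rowsum(cbind(Re(z), Im(z), I, 1), gid)
    first <- !duplicated(gid)
    hkl <- hkl[first, , drop = FALSE]
    I <- agg[, 3] / agg[, 4]
    ph <- atan2(agg[, 2], agg[, 1]) * 180 / pi
    tilt <- tilt[first]
  }
  reflection_set(hkl, I, ph, cell, sg, tilt = tilt)
}
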