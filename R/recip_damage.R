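## Reciprocal-space simulator of radiation-damaged, incomplete, phase-noisy
## reflection data sets, and the merging-success parameter sweep built on it.
##
## A reference structure-factor set is "collected" as a dose-symmetric tilt
## series: the crystal is randomly oriented, each reflection is assigned to
## the tilt image whose central slice passes nearest its reciprocal-space
## position, intensities decay with accumulated dose (image number times a
## relative B factor), the strongest reflections are retained to a target P1
## completeness, phases receive Gaussian errors, and the whole set gets a
## random fractional origin shift.

#' Dose-symmetric tilt acquisition order
#'
#' Tilt angles in acquisition order 0, -d, +d, -2d, +2d, ... spanning
#' `[-max_tilt, +max_tilt]` with increment `d`.
#'
#' @param max_tilt maximum tilt in degrees (e.g. 60).
#' @param increment tilt increment in degrees (e.g. 3).
#' @return data frame with `angle` (degrees) and `n` (image number, 1-based
#'   acquisition index).
#' @export
dose_symmetric_order <- function(max_tilt, increment) {
  k <- seq_len(round(max_tilt / increment))
  ang <- c(0, as.vector(rbind(-k, k)) * increment)
  data.frame(angle = ang, n = seq_along(ang))
}

#' Assign reflections to tilt images
#'
#' For a crystal rotated by `orientation` (3x3 matrix acting on laboratory
#' coordinates; beam along z, tilt axis along x), each reflection's
#' reciprocal-space position crosses the central slice of the image tilted by
#' `theta* = atan2(-v_z, v_y)` (folded to (-90, 90]). Reflections whose
#' crossing angle falls outside the scheme's range (plus `halfwidth`) lie in
#' the missing wedge.
#'
#' @param hkl integer matrix (n x 3).
#' @param cell a `unit_cell`.
#' @param orientation 3x3 rotation matrix.
#' @param scheme tilt scheme from [dose_symmetric_order()].
#' @param halfwidth capture half-width around each tilt angle in degrees
#'   (default: half the increment, so the in-range angular band is contiguous).
#' @return data frame with `theta` (crossing angle), `tilt` (assigned image
#'   angle, NA in the wedge), and `n` (image number, NA in the wedge).
#' @export
assign_tilt <- function(hkl, cell, orientation, scheme, halfwidth = NULL) {
  inc <- min(diff(sort(unique(scheme$angle))))
  if (is.null(halfwidth)) halfwidth <- inc / 2
  B <- reciprocal_basis(cell)
  v <- t(orientation %*% (B %*% t(hkl)))   # lab-frame reciprocal positions
  theta <- wrap_half_deg(atan2(-v[, 3], v[, 2]) * 180 / pi)
  k <- vapply(theta, function(th) which.min(abs(scheme$angle - th)), 1L)
  hit <- abs(scheme$angle[k] - theta) <= halfwidth
  data.frame(theta = theta,
             tilt = ifelse(hit, scheme$angle[k], NA_real_),
             n = ifelse(hit, scheme$n[k], NA_integer_))
}

#' Configuration for the reciprocal-space damage simulator
#'
#' @param mean_phase_error target mean absolute phase error in degrees.
#' @param completeness target P1 completeness (fraction of the full
#'   Friedel-unique reflection count to `d_min`, missing wedge included in the
#'   denominator).
#' @param b_rel relative B factor in Angstrom^2 per image: intensities decay
#'   as `exp(-(n * b_rel) * q^2 / 4)` with image number n.
#' @param max_tilt,increment tilt scheme parameters (degrees).
#' @param d_min resolution limit in Angstrom.
#' @return list of class `recip_damage_config`.
#' @export
recip_damage_config <- function(mean_phase_error = 0, completeness = 0.4,
                                b_rel = 0, max_tilt = 60, increment = 3,
                                d_min = 3.3) {
  stopifnot(mean_phase_error >= 0, completeness > 0, completeness <= 1,
            b_rel >= 0, max_tilt > 0, increment > 0, d_min > 0)
  structure(list(mean_phase_error = mean_phase_error,
                 completeness = completeness, b_rel = b_rel,
                 max_tilt = max_tilt, increment = increment, d_min = d_min),
            class = "recip_damage_config")
}

#' Simulate one damaged, incomplete, phase-shifted data set
#'
#' Applies the reciprocal-space damage model to a reference structure-factor
#' set: random crystal orientation, tilt assignment (missing wedge removed),
#' dose-dependent intensity decay `I = I0 exp(-(n b_rel) q^2 / 4)`, retention
#' of the highest-intensity reflections to the target P1 completeness,
#' Gaussian phase errors with `sd = mean_phase_error * sqrt(pi/2)` (so the
#' mean absolute error matches the target), and a random fractional origin
#' shift.
#'
#' @param ref reference `reflection_set` (full structure factors).
#' @param config a `recip_damage_config`.
#' @param seed RNG seed for this data set.
#' @return list with `rs` (the simulated `reflection_set`, tilt angles
#'   filled), `u_true` (the applied fractional shift), `orientation` (3x3
#'   rotation), and `js` (Jensen-Shannon tilt-distribution distance).
#' @export
simulate_damaged_dataset <- function(ref, config, seed) {
  set.seed(seed)
  scheme <- dose_symmetric_order(config$max_tilt, config$increment)
  Q <- random_rotation()
  at <- assign_tilt(ref$hkl, ref$cell, Q, scheme)
  keep <- which(!is.na(at$n))
  if (length(keep) < 4) stop("almost all reflections in the missing wedge")
  rs <- rs_subset(ref, keep)
  rs$tilt <- at$tilt[keep]
  n_img <- at$n[keep]
  q <- hkl_q(rs$hkl, rs$cell)
  rs$I <- rs$I * exp(-(n_img * config$b_rel) * q^2 / 4)
  ## retain strongest reflections to the target P1 completeness; the
  ## denominator is the full Friedel-unique count, wedge included
  n_full <- nrow(enumerate_hkl(ref$cell, config$d_min))
  n_target <- max(4, round(config$completeness * n_full))
  if (n_target < n_reflections(rs)) {
    ord <- order(rs$I, decreasing = TRUE)[seq_len(n_target)]
    rs <- rs_subset(rs, sort(ord))
  }
  u_true <- stats::runif(3)
  rs <- phase_shift(rs, u_true)
  if (config$mean_phase_error > 0) {
    sd_err <- config$mean_phase_error * sqrt(pi / 2)
    rs$phase <- wrap_deg(rs$phase + stats::rnorm(n_reflections(rs), 0, sd_err))
  }
  list(rs = rs, u_true = u_true, orientation = Q,
       js = js_distance(rs$tilt, max_tilt = 60))
}

#' Jensen-Shannon distance of a tilt-angle distribution from uniform
#'
#' Bins the recorded tilt angles (1-degree bins spanning `[-max_tilt,
#' +max_tilt]`), compares the normalized counts with the uniform reference
#' over the same range, and returns the square root of the Jensen-Shannon
#' divergence (base-2 logarithms, so the value lies in [0, 1]).
#'
#' @param tilts tilt angles in degrees (one per reflection; NAs dropped).
#' @param max_tilt reference half-range in degrees (default 60).
#' @param bin bin width in degrees (default 1).
#' @return numeric scalar in [0, 1].
#' @export
js_distance <- function(tilts, max_tilt = 60, bin = 1) {
  tilts <- tilts[!is.na(tilts)]
  if (!length(tilts)) return(1)
  breaks <- seq(-max_tilt - bin / 2, max_tilt + bin / 2, by = bin)
  tilts <- pmin(pmax(tilts, -max_tilt), max_tilt)
  p <- tabulate(findInterval(tilts, breaks, rightmost.closed = TRUE),
                nbins = length(breaks) - 1)
  p <- p / sum(p)
  q <- rep(1 / length(p), length(p))
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

#' Merging-success parameter sweep
#'
#' For each condition (mean phase error x P1 completeness x relative B
#' factor) simulates `pairs_per_condition` pairs of damaged data sets from
#' one reference structure, then evaluates three strategies per pair:
#' \describe{
#'   \item{common}{pairwise common-origin alignment; success when the
#'     fractional merge error against the true relative shift is below
#'     `threshold`.}
#'   \item{single}{crystallographic-origin search on each individual set
#'     (two trials per pair); success when the found shift lands within
#'     `threshold` of a permissible origin image of the true shift.}
#'   \item{merged}{the pair is merged onto a common origin, then the
#'     crystallographic-origin search is run on the merged set.}
#' }
#'
#' @param ref reference `reflection_set` (e.g. from [structure_factors()]).
#' @param phase_errors,completenesses,b_rels condition grids.
#' @param pairs_per_condition pairs simulated per condition.
#' @param seed master seed; per-data-set seeds are derived deterministically.
#' @param interval origin sampling interval in Angstrom (default 0.2).
#' @param threshold fractional-error success threshold (default 0.03,
#'   corresponding to twice a 0.2 Angstrom sampling interval for cells of
#'   this size).
#' @param d_min resolution limit in Angstrom.
#' @param verbose print a line per condition.
#' @return data frame with one row per pair: the condition, JS distances,
#'   merge errors and logical successes `common_ok`, `single_ok_a`,
#'   `single_ok_b`, `merged_ok`.
#' @export
merging_success_sweep <- function(ref,
                                  phase_errors = c(0, 10, 20, 30, 40),
                                  completenesses = c(0.1, 0.2, 0.3, 0.4),
                                  b_rels = c(0, 1, 2.5, 5),
                                  pairs_per_condition = 3,
                                  seed = 1, interval = 0.2, threshold = 0.03,
                                  d_min = 3.3, verbose = FALSE) {
  grid <- expand.grid(pe = phase_errors, comp = completenesses, b = b_rels)
  rows <- vector("list", nrow(grid) * pairs_per_condition)
  r <- 0
  for (g in seq_len(nrow(grid))) {
    cfg <- recip_damage_config(grid$pe[g], grid$comp[g], grid$b[g],
                               d_min = d_min)
    for (p in seq_len(pairs_per_condition)) {
      ## derived seeds kept below 2^31
      base <- (seed * 7919 + g * 1009 + p * 7) %% 2147483629
      a <- simulate_damaged_dataset(ref, cfg, base + 1)
      b <- simulate_damaged_dataset(ref, cfg, base + 2)
      row <- evaluate_pair(a, b, ref$sg, interval, threshold)
      r <- r + 1
      rows[[r]] <- cbind(data.frame(phase_error = grid$pe[g],
                                    completeness = grid$comp[g],
                                    b_rel = grid$b[g], pair = p), row)
    }
    if (verbose)
      message(sprintf("condition %d/%d done", g, nrow(grid)))
  }
  do.call(rbind, rows)
}

## score the three origin-finding strategies on one simulated pair
evaluate_pair <- function(a, b, sg, interval, threshold) {
  al <- tryCatch(origin_alignment(a$rs, b$rs, interval = interval),
                 error = function(e) NULL)
  u_rel <- a$u_true - b$u_true
  common_err <- if (is.null(al)) NA_real_ else merge_error(al$u, u_rel)
  single_err <- vapply(list(a, b), function(d) {
    fo <- find_crystallographic_origin(d$rs, interval = interval)
    origin_set_distance(fo$u + d$u_true, sg)
  }, numeric(1))
  merged_err <- NA_real_
  if (!is.null(al)) {
    mg <- tryCatch(merge_datasets(list(a$rs, b$rs), interval = interval),
                   error = function(e) NULL)
    if (!is.null(mg)) {
      fo <- find_crystallographic_origin(mg$merged, interval = interval)
      merged_err <- origin_set_distance(fo$u + a$u_true, sg)
    }
  }
  data.frame(js_a = a$js, js_b = b$js,
             n_a = n_reflections(a$rs), n_b = n_reflections(b$rs),
             common_err = common_err,
             single_err_a = single_err[1], single_err_b = single_err[2],
             merged_err = merged_err,
             common_ok = !is.na(common_err) & common_err < threshold,
             single_ok_a = single_err[1] < threshold,
             single_ok_b = single_err[2] < threshold,
             merged_ok = !is.na(merged_err) & merged_err < threshold)
}

#' Success-rate comparison from a sweep table
#'
#' Aggregates a [merging_success_sweep()] result into the two headline
#' percentages: the difference between the pairwise common-origin success
#' rate and the single-set crystallographic-origin success rate, and the
#' increase of the merged-pair crystallographic-origin success rate over the
#' single-set rate.
#'
#' @param sweep data frame from [merging_success_sweep()].
#' @return list with `common_minus_single` and `merged_minus_single`
#'   (percentage points), plus the three underlying rates.
#' @export
sweep_success_rates <- function(sweep) {
  common <- mean(sweep$common_ok)
  single <- mean(c(sweep$single_ok_a, sweep$single_ok_b))
  merged <- mean(sweep$merged_ok)
  list(common_minus_single = 100 * (common - single),
       merged_minus_single = 100 * (merged - single),
       rate_common = common, rate_single = single, rate_merged = merged)
}
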