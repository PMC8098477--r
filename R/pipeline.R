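## Top-level pipeline: preprocess -> findspots -> index -> extract ->
## merge -> origin -> reduce -> metrics, with per-stage provenance logging.

#' Pipeline configuration
#'
#' Builds a validated configuration list for [run_pipeline()]. Each stage has
#' its own section; all defaults equal the package's standard processing
#' values (0.5 taper fraction, 4-sigma peak / 2-sigma background thresholds,
#' 2-voxel centroid tolerance, 15 degree phase-spread limit, 0.2 Angstrom
#' origin sampling, 3.3 Angstrom resolution limit).
#'
#' @param volumes list of `volume` objects (tomograms) or paths to MRC files.
#'   With more than one volume the data sets are merged onto a common origin
#'   before the crystallographic-origin search.
#' @param sg space group symbol (e.g. "P212121").
#' @param seed integer seed logged and applied before any stochastic stage.
#' @param tilt_range half-range of the tilt series in degrees.
#' @param preprocess list: `taper_fraction`.
#' @param findspots list: `gain`, `pixel_limits`, `beam_radius`.
#' @param index list: `period_range`, `n_dirs`, `max_violation`.
#' @param extract list passed to [extraction_config()].
#' @param origin list: `interval`, `method`, `top_k`, `top_skew`.
#' @param metrics list: `d_min`.
#' @param reference optional `reflection_set` of model structure factors; if
#'   given, reference metrics (phase residual, intensity and map
#'   correlations) are computed in the metrics stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(volumes, sg, seed = 1, tilt_range = 60,
                            preprocess = list(), findspots = list(),
                            index = list(), extract = list(),
                            origin = list(), metrics = list(),
                            reference = NULL) {
  fill <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  if (!is.list(volumes) || !length(volumes))
    stop("config: 'volumes' must be a non-empty list")
  structure(list(
    volumes = volumes,
    sg = space_group(sg)$symbol,
    seed = as.integer(seed),
    tilt_range = tilt_range,
    preprocess = fill(preprocess, list(taper_fraction = 0.5)),
    findspots = fill(findspots, list(gain = 6, pixel_limits = c(3, 300),
                                     beam_radius = 3)),
    index = fill(index, list(period_range = c(10, 60), n_dirs = 1500,
                             max_violation = 0.05)),
    extract = fill(extract, list(radius = 7, peak_sigma = 4,
                                 background_sigma = 2, centroid_tol = 2,
                                 phase_std_max = 15, d_min = 3.3)),
    origin = fill(origin, list(interval = 0.2, method = "hierarchical",
                               top_k = 1024, top_skew = 64)),
    metrics = fill(metrics, list(d_min = 3.3)),
    reference = reference
  ), class = "pipeline_config")
}

## run one stage with provenance capture; any error halts the pipeline with
## the stage name while earlier artifacts stay available to the caller
pipeline_stage <- function(state, name, params, fun) {
  t0 <- Sys.time()
  res <- tryCatch(fun(state), error = function(e)
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
  res$log[[length(res$log) + 1]] <- list(
    stage = name, params = params, seed = res$config$seed,
    elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  res
}

#' Run the full processing pipeline
#'
#' Executes, in order: preprocess (density centering, Tukey taper, Fourier
#' transform), findspots, index (lattice search plus space-group cell
#' refinement), extract (Bragg peak extraction into a reflection set, one per
#' input volume), merge (pairwise common-origin alignment onto the first
#' set, for multiple volumes), origin (crystallographic-origin search and
#' phase shift), reduce (reduction to the asymmetric unit) and metrics.
#' Every stage appends its parameters and the seed to the provenance log; a
#' stage failure halts with an error naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return list with `datasets` (per-volume reflection sets), `merged`,
#'   `origin` (search result), `reduced` (ASU reflection set), `indexing`
#'   (per-volume solutions), `metrics`, and `log` (provenance entries).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  set.seed(config$seed)
  state <- list(config = config, log = list())

  state <- pipeline_stage(state, "preprocess", config$preprocess, function(s) {
    s$fvs <- lapply(config$volumes, function(v) {
      if (is.character(v)) v <- read_mrc(v)
      v <- center_density(v)$vol
      v <- taper(v, fraction = config$preprocess$taper_fraction)
      fourier_transform(v)
    })
    s
  })

  state <- pipeline_stage(state, "findspots", config$findspots, function(s) {
    p <- config$findspots
    s$spots <- lapply(s$fvs, function(fv)
      find_spots(fv, gain = p$gain, pixel_limits = p$pixel_limits,
                 beam_radius = p$beam_radius))
    for (sp in s$spots) if (nrow(sp) < 6) stop("too few spots (", nrow(sp), ")")
    s
  })

  state <- pipeline_stage(state, "index", config$index, function(s) {
    p <- config$index
    s$indexing <- Map(function(sp, fv) {
      sol <- index_lattice(sp, fv$dq, period_range = p$period_range,
                           n_dirs = p$n_dirs)
      refine_cell_symmetry(sol, config$sg, max_violation = p$max_violation)
    }, s$spots, s$fvs)
    s
  })

  state <- pipeline_stage(state, "extract", config$extract, function(s) {
    cfg <- do.call(extraction_config, config$extract)
    s$datasets <- Map(function(sol, fv) {
      pk <- predict_peaks(sol, fv$dq, cfg$d_min, tilt_range = config$tilt_range)
      pk <- pk[!pk$in_wedge, , drop = FALSE]
      obs <- lapply(seq_len(nrow(pk)), function(i)
        extract_peak(fv, c(pk$h[i], pk$k[i], pk$l[i]),
                     c(pk$x[i], pk$y[i], pk$z[i]), cfg))
      rs <- collect_reflections(obs, sol$cell, config$sg)
      if (!nrow(rs$hkl)) stop("no accepted reflections")
      rs
    }, s$indexing, s$fvs)
    s
  })

  state <- pipeline_stage(state, "merge", config$origin["interval"], function(s) {
    if (length(s$datasets) > 1) {
      mg <- merge_datasets(s$datasets, interval = config$origin$interval)
      s$merged <- mg$merged
      s$merge_shifts <- mg$shifts
    } else {
      s$merged <- s$datasets[[1]]
    }
    s
  })

  state <- pipeline_stage(state, "origin", config$origin, function(s) {
    p <- config$origin
    s$origin <- find_crystallographic_origin(
      s$merged, interval = p$interval, method = p$method,
      top_k = p$top_k, top_skew = p$top_skew)
    s$shifted <- phase_shift(s$merged, s$origin$u)
    s
  })

  state <- pipeline_stage(state, "reduce", list(), function(s) {
    s$reduced <- reduce_to_asu(s$shifted)
    s
  })

  state <- pipeline_stage(state, "metrics", config$metrics, function(s) {
    d_min <- config$metrics$d_min
    m <- list(n_reflections = nrow(s$merged$hkl),
              n_unique = nrow(s$reduced$hkl),
              completeness_P1 = completeness(s$merged, d_min, "P1"),
              completeness_sg = completeness(s$reduced, d_min, "sg"))
    ref <- config$reference
    if (!is.null(ref)) {
      ## report against the best-matching permissible origin of the reference
      orgs <- permissible_origins(s$reduced$sg)$points
      scores <- apply(orgs, 1, function(u)
        phase_residual_ref(phase_shift(s$reduced, u), ref))
      best <- which.min(scores)
      rs_best <- phase_shift(s$reduced, orgs[best, ])
      m$phase_residual <- scores[best]
      m$intensity_cc <- intensity_cc(rs_best, ref)
      m$map_cc <- map_cc(rs_best, ref)
    }
    s$metrics <- m
    s
  })

  state[c("datasets", "merged", "origin", "reduced", "indexing",
          "metrics", "log")]
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline config: %d volume(s), space group %s, seed %d\n",
              length(x$volumes), x$sg, x$seed))
  invisible(x)
}
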