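# tomoxtal

Crystallographic structure-factor intensities **and phases** from cryo-electron
tomograms of protein nanocrystals.

## The problem

Electron cryo-tomography records a tilt series of projection images of a
specimen and reconstructs a 3D volume. When the specimen is a tiny protein
crystal, the Fourier transform of that volume contains Bragg peaks, and — unlike
diffraction data — each peak carries a measurable *phase*. In principle a
tomogram therefore yields experimentally phased crystallographic data.

In practice several obstacles intervene:

* the reconstruction's density is split across box boundaries, which scrambles
  Bragg-peak phases unless the volume is re-centered and tapered first;
* the crystal orientation is unknown, so the reciprocal lattice must be found
  and indexed from the peak positions alone;
* the tilt range is limited (a *missing wedge* of unmeasured reciprocal space)
  and radiation damage attenuates high-resolution intensities as the series
  progresses, so any one tomogram gives incomplete, noisy data;
* each data set carries an arbitrary phase origin: two data sets (or one data
  set and the crystallographic convention) can only be compared after finding
  the translation that aligns their origins.

`tomoxtal` implements the full chain — simulation, preprocessing, spot finding,
indexing, peak extraction, merging, phase-origin searches, reduction, and
evaluation metrics — in R, with the inner grid searches in C++ (Rcpp). All
stages work on synthetic data generated by the package itself, so everything is
testable end to end without external inputs.

## Worked example

A complete run on a small synthetic crystal (about a minute on one CPU):

```r
library(tomoxtal)

## a small P212121 crystal: pseudo-atomic model, 4 x 4 x 3 unit cells
set.seed(7)
cell  <- unit_cell(10, 12, 14)
model <- generate_pseudo_structure(seed = 5, n_atoms = 4, cell, "P212121")
vol   <- embed_crystal(build_crystal_density(model, cell, voxel = 0.8,
                                             n_cells = c(4, 4, 3)))

## dose-symmetric tilt series (+/-60 degrees, 3-degree increment) and
## weighted-back-projection reconstruction
scheme <- dose_symmetric_order(60, 3)
ts     <- damaged_tilt_series(vol, scheme)
tomo   <- reconstruct_tomogram(ts$projections, ts$angles, 0.8)

## the full pipeline, scored against the known structure factors
ref <- structure_factors(model, cell, "P212121", d_min = 2.5)
cfg <- pipeline_config(list(tomo), "P212121", seed = 3,
                       findspots = list(gain = 4),
                       index     = list(period_range = c(7, 30)),
                       extract   = list(d_min = 2.5),
                       metrics   = list(d_min = 2.5),
                       reference = ref)
out <- run_pipeline(cfg)

print(out$indexing[[1]]$cell)
str(out$metrics)
```

Output from this exact script:

```
unit cell: a=10.148 b=12.096 c=14.233  alpha=90.00 beta=90.00 gamma=90.00
List of 7
 $ n_reflections  : int 92
 $ n_unique       : int 39
 $ completeness_P1: num 0.402
 $ completeness_sg: num 0.448
 $ phase_residual : num 30
 $ intensity_cc   : num 0.104
 $ map_cc         : num 0.414
```

The indexing stage recovered the 10 x 12 x 14 Å cell to within half a percent
from the Bragg-peak positions alone, and the extracted phases agree with the
model's structure factors to a mean residual of 30° after the crystallographic
origin was located — entirely from the tomogram.

Every stage is also available as a standalone function (`find_spots`,
`index_lattice`, `extract_peak`, `merge_datasets`,
`find_crystallographic_origin`, `reduce_to_asu`, ...), and as subcommands of
the command-line tool:

```sh
Rscript inst/cli/tomoxtal.R simulate --cell 10,12,14 --sg P212121 --out crystal.mrc
Rscript inst/cli/tomoxtal.R index --input spots.csv --dq 0.005882 --sg P212121
```

## The merging study

The package includes a reciprocal-space simulator of damaged, incomplete,
phase-noisy data sets (`simulate_damaged_dataset`) and a sweep driver
(`merging_success_sweep`) that compares three strategies over a grid of mean
phase errors (0–40°), P1 completeness (10–40%) and relative B factors, on an
orthorhombic 16.2 x 29.1 x 47.7 Å P2₁2₁2₁ cell with 0.2 Å origin sampling:

1. finding a **common origin** between two data sets,
2. finding the **crystallographic origin** of each single data set,
3. finding the crystallographic origin of the **merged** pair.

Success means the recovered origin lies within twice the sampling interval.
Pairwise common-origin alignment succeeds slightly more often than single-set
crystallographic-origin location, and merging two data sets before the origin
search raises the success rate further — the quantitative motivation for
merging tomographic crystallography data.

## Reproduction

`scripts/acceptance.R` runs the full study against the installed package and
writes the two headline numbers as JSON (`t8`: common-origin minus single-set
success rate; `t9`: merged-pair minus single-set success rate, both in
percentage points over 240 simulated pairs):

```sh
Rscript scripts/acceptance.R --seed 202 --out results.json
```

All randomness derives from `--seed`. The run takes roughly 12–15 minutes on
one CPU. With seed 202 we obtained `t8 = +3.96`, `t9 = +6.46` (both positive:
the merged-pair search is the most reliable of the three; individual values
fluctuate by a few percentage points between seeds at this replicate count).

The test suite (including the acceptance criteria in
`tests/testthat/test-acceptance.R`) runs with:

```r
testthat::test_dir("tests/testthat", package = "tomoxtal",
                   load_package = "installed")
```

## Package layout

| Area | Files |
|---|---|
| Cells, symmetry, reflections | `R/cell.R`, `R/symmetry.R`, `R/reflections.R` |
| Real-space simulation | `R/sim_crystal.R`, `R/volume.R` |
| Reciprocal-space damage simulator | `R/recip_damage.R` |
| Preprocess / spots / indexing | `R/preprocess.R`, `R/indexing.R` |
| Peak extraction | `R/peak_extraction.R` |
| Merging and origin searches | `R/merging.R`, `R/origin_search.R` |
| Metrics and maps | `R/metrics.R` |
| Pipeline, I/O, CLI | `R/pipeline.R`, `R/io.R`, `inst/cli/tomoxtal.R` |
| C++ kernels | `src/kernels.cpp` |
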