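---
title: "Methods: phases, origins and merging in tomographic crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phases, origins and merging in tomographic crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the conventions and algorithms used by `tomoxtal`. All
code chunks are illustrative and not evaluated when the vignette is built.

## Conventions

Symmetry operations act on fractional coordinates as row-vector pairs
$x' = xR + t$ (so Miller indices transform as $h' = hR$). For a structure
factor $F(h) = |F| e^{i\varphi}$ with phases in degrees:

* **Translation (phase-origin shift)** by a fractional vector $u$:
  $\varphi'(h) = \varphi(h) - 360\, h\cdot u$. Implemented by `phase_shift()`.
* **Symmetry transport**: $\varphi(hR) = \varphi(h) - 360\, h\cdot t$.
* **Friedel mates**: $\varphi(-h) = -\varphi(h)$ for real density.
* **Centric reflections** ($hR = -h$ for some operation) can only take two
  phases, $\theta$ and $\theta + 180$ with $\theta = 180\,(h\cdot t) \bmod
  180$. `centric_info()` reports both.

All phases are wrapped to $(-180, 180]$. Because $+180$ and $-180$ (and $0$
and $-0$) are the same angle but different doubles, tests and residuals always
compare phases modulo 360.

## Permissible origins

Two descriptions of the same crystal may differ by any translation $v$ that
maps the symmetry framework onto itself: $(R - I)v \in \mathbb{Z}^3$ for every
operation. For $P2_12_12_1$ this gives the eight points $\{0, \tfrac12\}^3$
with no free axes; for polar groups one axis is continuous.
`permissible_origins()` enumerates the lattice points and free axes, and
`origin_set_distance()` measures the minimal-image distance of a fractional
vector from the nearest permissible origin — the success metric of the
merging study.

## Origin searches

Both searches score candidate shifts on a fractional grid whose spacing is at
least as fine as the requested interval (0.2 Å by default; grid sizes are
rounded up to 5-smooth integers so FFTs stay fast).

**Common origin between two sets** (`origin_alignment`): the weighted phase
coherence $\sum_m w_m \cos(\Delta\varphi_m + 360\, h_m\cdot u)$ over shared
reflections is, as a function of $u$, a Fourier series whose coefficients sit
at the shared $h_m$ — one inverse FFT scores the whole grid. The top
candidates are re-scored with the exact weighted mean absolute residual and
the minimum is returned.

**Crystallographic origin of one set** (`find_crystallographic_origin`)
combines three scores:

1. *symmetry residual*: after shifting by $u$, phases transported from
   symmetry-equivalent observed reflections must agree;
2. *centric residual*: shifted centric phases must sit on their allowed pair
   of values (compared modulo 180);
3. *map skew*: the skewness of the symmetrized density map synthesized from
   the shifted set — the correct origin yields the characteristic
   positive-skewed protein density.

An FFT coherence prefilter shortlists candidates, the exact residuals are
evaluated on the shortlist, the map skew on the best few dozen, and the
z-score combination picks the winner. In $P1$ every origin is permissible and
the search returns $u = 0$ with a note; a set with no symmetry-related pairs
and no centrics raises an error ("not determinable").

## Merging

`merge_datasets()` merges greedily: the first set is the reference; each
further set is aligned (`origin_alignment`), rescaled (`scale_intensities`,
which fits $\log(I/I_{\mathrm{ref}}) = b + mq - q^2\sigma^2/2$, a
Debye–Waller-type model) and combined. Merged phases are intensity-weighted
circular means; multiplicities count observations.

## Reciprocal-space damage simulator

`simulate_damaged_dataset()` degrades a reference set the way a real
tilt-series acquisition would:

* dose-symmetric acquisition order ($0, -\delta, +\delta, -2\delta, \dots$);
  each reflection inherits the image number $n$ at which its effective tilt
  angle is recorded;
* intensity decay $I = I_0\, e^{-(n\, B_\mathrm{rel})\, q^2/4}$;
* reflections beyond the tilt range fall in the missing wedge; completeness
  is then reduced to the target by keeping the strongest reflections;
* a random phase-origin shift and Gaussian phase noise with
  $\sigma = \bar\varepsilon\sqrt{\pi/2}$ (so $\bar\varepsilon$ is the mean
  absolute error).

`merging_success_sweep()` runs pairs of such sets over a grid of phase
errors, completeness and relative B factors and records, for each pair, the
success of the common-origin, single-set and merged-set searches.

## Tilt-spread diagnostic

`js_distance()` bins recorded tilt angles into 1° bins over the full range
and returns the Jensen–Shannon distance (square root of the JS divergence,
base-2 logarithms) from the uniform distribution: 0 for perfectly even
coverage, 1 for an empty set. Low values indicate the even angular coverage
that favors origin determination.

## Peak extraction

`extract_peak()` measures one predicted Bragg peak in the Fourier transform
of a preprocessed tomogram: sigma-clipped background statistics in a
subvolume, a 4σ detection / 2σ integration mask, a 2-voxel centroid
tolerance (else "partial"), directional background interpolation under the
mask, and an intensity-weighted circular phase mean whose outliers are
removed iteratively until the weighted spread is at most 15°. If coherence
is only achievable by discarding more than half of the peak pixels the peak
is rejected as "phase_incoherent". Because the integration mask is a value
threshold, it excludes the Gaussian tail below that level; the summed
intensity is rescaled by the retained mass fraction of an isotropic Gaussian
truncated at the threshold, which removes the systematic underestimate for
weak peaks.

## Preprocessing

Weighted-back-projection tomograms place the crystal wherever the specimen
was; the Fourier phase of each Bragg peak then oscillates across the peak
unless the density is centered. `center_density()` finds the density center
via the autoconvolution (its peak sits at twice the center) disambiguated by
the center of mass, and shifts it to the grid's phase origin
(`floor(dims/2)`, 0-based). `taper()` applies a separable Tukey window
(flat center, cosine flanks) so box edges do not leak spectral power into
the peaks.

## End-to-end use

```{r}
library(tomoxtal)
cfg <- pipeline_config(volumes = list(tomo), sg = "P212121", seed = 1,
                       reference = ref)
out <- run_pipeline(cfg)
out$metrics
```

See the README for a complete worked example with its output.
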