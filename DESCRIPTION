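Package: tomoxtal
Title: Crystallographic Intensities and Phases from Tomograms of Protein Nanocrystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recovering crystallographic structure-factor intensities
    and phases from (simulated) cryo-electron tomograms of protein nanocrystals.
    Provides a synthetic-data backbone (pseudo-atomic models, nanocrystal
    densities, dose-symmetric tilt series, weighted-back-projection tomograms,
    and two radiation-damage simulators), preprocessing that eliminates phase
    splitting at Bragg peaks (Tukey tapering plus auto-convolution centering),
    spot finding and 1D-FFT lattice indexing, heuristic Bragg-peak intensity and
    phase extraction, multi-dataset phase-origin alignment and merging,
    crystallographic phase-origin location with symmetry, centric and map-skew
    scoring, reduction to the asymmetric unit, evaluation metrics, and a
    Jensen-Shannon tilt-spread diagnostic for data-collection strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    optparse,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
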