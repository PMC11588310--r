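Package: cystpuncta
Title: Puncta Detection and Object-Based Co-Occurrence in 3D Light-Sheet
    Volumes of Toxoplasma Cysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies autophagy-related puncta in multi-channel, multi-timepoint
    3D fluorescence volumes of Toxoplasma gondii bradyzoite cysts imaged by
    lattice light sheet microscopy. Provides shear-based deskewing, control-derived
    background and spectral bleed-through correction, a spacing-aware band-pass
    particle enhancer with seeded region growing for 3D blob segmentation, an
    intensity-based cyst segmenter, volume filtering, object-based co-occurrence
    ratios between channel pairs, and replicate-level aggregation with paired
    t-tests. A synthetic volume generator with full ground truth (punctum centers,
    radii, co-occurrence partners, background and bleed-through parameters) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
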