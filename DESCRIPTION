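Package: gliaSlice
Title: Electrophysiology and Microglia Morphometry for Organotypic Slice Cultures
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for neuroimmunology experiments in hippocampal
    slice cultures: Welch power spectral density and network-state
    classification of local field potential recordings (gamma oscillations,
    low activity, neural bursting, no activity), prominence-based burst
    detection with burst-triggered analytic Morlet wavelet averaging,
    intracellular action-potential and afterhyperpolarization metrics,
    automated Iba1/DAPI microglia counting and watershed/skeleton/Sholl
    morphometry, and immunoassay standard-curve construction and inversion.
    Includes seeded synthetic-data generators with ground truth for every
    input class, enabling parameter-recovery validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    EBImage,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
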