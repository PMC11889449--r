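Package: mixnmr
Title: Simulation of 1D and 2D 1H NMR Spectra of Biofluid Metabolite Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates realistic one-dimensional 1H, two-dimensional
    J-resolved and COSY NMR spectra of biofluid-like metabolite mixtures
    (urine, blood, cerebrospinal fluid) as linear combinations of pure
    compound reference spectra. Supports case-control and
    continuous-outcome cohort designs with inter-metabolite correlations,
    truncated-normal concentration sampling from HMDB-style biofluid
    statistics, pH-dependent peak shifting driven by a
    Henderson-Hasselbalch transform, and a broad albumin-like protein
    background for blood. Includes a fully synthetic pure-compound
    fixture generator so the complete pipeline runs without external
    spectral libraries, plus on-disk library I/O and a command-line
    driver for reproducible cohort simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
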