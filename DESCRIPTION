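Package: pscore
Title: Peak Scoring for Metabolite Identification and Quantification in
    GC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies and quantifies metabolites in GC-MS samples by
    scoring candidate retention times against a user-supplied spectral
    library. For every library compound the four most abundant ion mass
    fragments are scored in three stages (peak co-occurrence, relative
    intensity match within a match-factor interval, and pairwise Pearson
    correlation of fragment traces), candidate retention times compete on
    the summed score, and per-sample identifications are merged into
    cross-sample abundance tables suitable for downstream metabolomics
    statistics. Includes readers for mzML, ANDI-MS/netCDF (via mzR) and a
    plain delimited scan format, an AMDIS .msl library parser, a
    synthetic-chromatogram generator with known ground truth, and a Welch
    t-test biomarker screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
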