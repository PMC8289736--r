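Package: sipsims
Title: DNA-SIP Heavy-Fraction Detection and NanoSIMS Single-Cell Isotope
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two complementary stable-isotope-probing analyses of
    microbial communities. The first detects 13C-labelled amplicon sequence
    variants (ASVs) from CsCl buoyant-density gradient fraction profiles by
    windowed rank-based group comparisons between 13C and 12C treatments,
    and substrate-responsive ASVs from replicated microcosm time series.
    The second quantifies per-cell 13C atom fractions from NanoSIMS
    multilayer ion-count images, including detector dead-time correction,
    integer-pixel drift alignment, ratio-of-sums region-of-interest
    statistics, Poisson counting-error propagation, and a dual-criterion
    enrichment call against a natural-abundance control. Synthetic-data
    generators with known ground truth make every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
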