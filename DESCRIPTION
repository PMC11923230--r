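Package: floralshift
Title: Multilevel Analysis of Intraspecific Red-to-Yellow Floral Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of within-species floral colour
    transitions and incipient pollinator shifts. Implements a GC-MS volatile
    peak-filter cascade with blank subtraction and contaminant screening,
    Kovats retention-index calibration and standard-curve quantification of
    emission rates; a trichromatic bee colour-hexagon model of floral
    reflectance with von Kries adaptation to a green background;
    electroantennogram (EAG) normalization against interleaved positive
    controls; chi-square goodness-of-fit statistics for pollinator choice
    trials; pigment, nectar and herkogamy phenotype derivations; all-pairs
    Pearson correlation censuses of floral trait integration; per-window
    variant-density tracks with Savitzky-Golay smoothing; and a seeded
    synthetic-data generator that emulates every input shape for testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
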