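Package: cemetab
Title: Untargeted CE-ESI-MS Metabolomics Pipeline for Infection Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable, tested processing pipeline for untargeted capillary
    electrophoresis electrospray ionization mass spectrometry (CE-ESI-MS)
    metabolomics, modelled on a host-pathogen infection study in Drosophila
    melanogaster larvae. Covers monoisotopic mass and adduct m/z arithmetic,
    extracted ion electropherogram (EIC) construction and peak detection with
    signal-to-noise gating, per-run internal m/z recalibration on
    sodium-formate clusters, third-order polynomial migration-time alignment
    against a packaged reference metabolite database, dual-tolerance (ppm and
    percent migration time) identification with confidence flags, abundance
    matrix assembly with replicate quality control, median normalization with
    log transform and autoscaling, sparse partial least squares discriminant
    analysis (sPLS-DA) with stratified cross-validation, and topology-aware
    pathway overrepresentation analysis. A synthetic-data generator emulating
    the study design stands in for instrument raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
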