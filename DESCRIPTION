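Package: stomap
Title: Mapping Subthreshold Voltage Oscillations in Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("stomap", "developers", email = "stomap@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wide-field voltage-sensitive dye imaging of
    subthreshold membrane-voltage oscillations (STOs), as expressed by
    gap-junction-coupled inferior olive networks. Provides per-pixel Welch
    power-spectral-density mapping in the 3-12 Hz STO band, density-based
    (OPTICS) clustering of synchronously oscillating pixels, sliding auto- and
    cross-correlograms against paired current-clamp electrophysiology,
    windowed covariance and coherence images, cross-power spectral density and
    pre/post-stimulation spectral comparison, and radial-profile
    quantification of dye spread and internalization in confocal images. A
    synthetic-data module generates ground-truth STO movies, paired
    electrophysiology and staining fields so that every stage is testable
    without raw recordings. Movies are read and written as multi-page TIFF;
    tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
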