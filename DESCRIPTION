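Package: msiKpuu
Title: Quantitative MALDI-MSI Neuropharmacokinetics of Unbound Drug Transport
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative MALDI mass spectrometry imaging (qMSI) of
    drugs in brain tissue sections and for neuropharmacokinetic estimation of
    unbound drug transport across the blood-brain barrier. Provides S4 data
    containers for pixel-grid ion images, region atlases, and on-tissue
    calibration layouts; internal-standard normalization; tissue-equivalent
    calibration with LOD/LLOQ; region-of-interest quantitation; estimation of
    the unbound brain-to-plasma partition coefficient (Kp,uu,brain and
    Kp,uu,ROI) and the unbound volume of distribution (Vu,brain) from paired
    in vivo and brain-slice sections; transport classification; statistical
    comparison of regions against the whole-section reference (Shapiro-Wilk
    gate, one-way ANOVA with Dunnett adjustment, t-tests, robust outlier
    flagging); and a synthetic-section generator with known ground truth so
    the whole chain can be exercised without instrument data. A minimal imzML
    reader is included for instrument-data ingestion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
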