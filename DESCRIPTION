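Package: qmsi
Title: Quantitative Mass Spectrometry Imaging with Mimetic Tissue Model
    Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibration and regional absolute quantification for
    targeted (MRM-based) mass spectrometry imaging of drugs in tissue.
    Implements mimetic tissue-array calibration with endogenous-lipid
    ratio normalization, blank-based limit-of-detection and
    lower-limit-of-quantification estimation, iterative below-LOD
    exclusion of calibration levels, quality-control precision and
    accuracy evaluation against bioanalytical characterization criteria,
    cell-density-corrected region-of-interest quantification with
    fold-difference and LC-MS concordance reporting, multi-instrument
    mode comparison tables, and a seeded synthetic DESI-MRM data
    generator for end-to-end validation. Native data formats are plain
    TSV channel grids with JSON sidecars; continuous and processed imzML
    can be imported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
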