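Package: epscreen
Title: Analysis of Arrayed CRISPR Knockout Electropermeabilization Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing arrayed CRISPR knockout screens of cell
    membrane electropermeabilization read out by per-cell Yo-Pro-1 dye
    uptake. Provides a synthetic-screen generator with known ground truth,
    an optional image-based quantification front end, sham-corrected and
    plate-normalized uptake summaries, hit calling by the strictly
    standardized mean difference (SSMD) combined with Dunnett's
    many-to-one test, replication-series concordance, a model of the T7
    endonuclease I genomic cleavage assay, adiabatic-heating dose
    bookkeeping with dose-response fitting, and correlation of gene
    expression with nanosecond-pulse lethality (LD50) across cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
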