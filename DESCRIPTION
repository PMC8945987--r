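Package: CMAtools
Title: Chaperone-Mediated Autophagy Substrate Screening and Activity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for chaperone-mediated autophagy (CMA) studies: scanning of
    protein sequences for KFERQ-like targeting pentapeptides with classification
    into canonical, phosphorylation-activated and acetylation-activated motif
    classes; filtering of SILAC lysosome-proteome quantification tables with
    fold-change, p-value and identification-quality criteria and up/down
    regulation calling; quantification of fluorescent CMA-reporter puncta per
    cell from two-channel microscopy images using nucleus-seeded watershed
    segmentation and Phansalkar local thresholding; and synthetic-data
    generators (quantification tables, motif-bearing sequences, benchmark cell
    images with ground truth) so that every stage of the pipeline can be
    validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
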