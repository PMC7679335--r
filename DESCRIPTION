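Package: gslms
Title: Glycosphingolipid MS/MS Annotation and Sphingolipid Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Negative-mode tandem mass spectrometry annotation of
    glycosphingolipids: monoisotopic precursor and glycosidic B/C/Y/Z
    fragment computation on glycan trees, isomer discrimination via
    automatically derived diagnostic ions, and in-silico Vibrio cholerae
    sialidase digestion (inner sialic acids resistant). Also implements the
    quantification stages of a sphingolipid profiling workflow:
    thin-layer-chromatography lane tables to composition profiles and
    genotype fold changes, detergent-resistant-membrane sucrose-gradient
    analysis, and fluorogenic 4-methylumbelliferone glycohydrolase activity
    assays with inhibitor-based resolution of lysosomal versus
    non-lysosomal glucosylceramidase. Seeded synthetic-data generators
    emulate every input format so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
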