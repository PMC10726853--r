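Package: mosaicmap
Title: Mosaic-Based Single-Subject Cortical Atrophy Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-subject cortical gray-matter atrophy assessment by the
    mosaic approach: parcel-averaged cortical thickness is rated against a
    healthy reference cohort with per-patch z-scores, exhaustive
    leave-one-as-singleton permutation p-values and family-wise error
    thresholding, yielding a per-patch thin/not-thin map and a scalar
    thin-patch fraction. Also provides the standard vertexwise baselines
    (Crawford-Howell singleton-versus-group tests with covariates, mesh
    smoothing, FDR and max-statistic permutation correction), nonparametric
    group-level patch contrasts, an evaluation layer comparing strategies by
    correlation with clinical variables, and a synthetic cohort simulator
    for testing without patient data. Reads and writes GIFTI surface scalar
    and label files as well as plain CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
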