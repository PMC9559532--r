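Package: etrgen
Title: Genetic Evaluation of Eye Temperature at Rest in Sport Horses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for the quantitative-genetic analysis of basal
    reactivity in sport horses measured as eye temperature at rest (ETR)
    by infrared thermography. Provides a synthetic-data generator
    (pedigree, coat colors, fixed-effect structure, breeding values,
    competition ranks), pedigree utilities (validation, ancestor tracing,
    numerator relationship matrix and its sparse inverse with inbreeding,
    unknown-parent genetic groups by ancestor coat color), phenotype-side
    statistics (one-way GLM F-tests, least-squares means with Duncan's
    multiple range test, Spearman rank correlation with competition rank),
    single-trait Bayesian animal models fitted by Gibbs sampling under a
    genetic-groups variant (MGG) and a heterogeneous-residual-variance
    variant (MHRV), and estimated-breeding-value reporting on the 80-120
    standardized scale with top-fraction selection and cross-model
    coincidence summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
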