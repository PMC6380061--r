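Package: prognet
Title: Prognostic Module Networks from Gene Co-Expression Data
Version: 0.1.0
Authors@R: person("Prognet", "Developers", email = "prognet@example.org",
    role = c("aut", "cre"))
Description: Identifies cancer prognostic gene modules by module network
    analysis. Builds a rank-based gene co-expression network (each gene linked
    to its k most correlated partners), detects dense modules with an
    MCODE-style clustering algorithm, links modules into a cross-talk network
    by permutation-testing inter-module edge counts, scores each module's
    prognostic stability by resampled univariate Cox regression, prioritizes
    modules with GeneRank (PageRank with a prognostic prior), and evaluates
    selected modules by risk-score survival stratification, log-rank tests,
    discrimination scores, and hypergeometric enrichment. Includes a synthetic
    expression/survival data generator with planted modules for end-to-end
    validation, and a pipeline driver with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
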