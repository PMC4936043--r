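Package: pteriomatrix
Title: Occupancy, Rate and Composition Engineering of Phylogenomic
    Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling amino-acid supermatrices from per-locus
    orthogroup alignments under gene-occupancy thresholds, ranking loci by
    a percent-pairwise-identity proxy for evolutionary rate, deriving
    cumulative and non-overlapping block submatrix series, screening
    matrices for compositional heterogeneity with relative composition
    frequency variability (RCFV), and tracing bootstrap support for named
    clade hypotheses across matrix series. Includes a protein-sequence
    simulator with per-locus rate multipliers, per-gene missingness and
    per-taxon compositional bias, and a minimal p-distance
    neighbour-joining bootstrap backend so the whole workflow runs
    end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
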