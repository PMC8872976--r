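Package: mddgrid
Title: Genetic Architecture of Combinatorial Major Depression Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the genetic architecture of major depression
    changes as diagnostic components (recurrence, five or more symptoms, long
    episode duration, functional impairment, persistence) are layered on a
    cardinal-symptom baseline. Enumerates the 32 combinatorial phenotype
    definitions and assigns case/control status, estimates liability-scale
    SNP heritability by Haseman-Elston/PCGC regression on a genomic
    relatedness matrix, computes LD scores and genetic correlations by LD
    score regression, and compares phenotypes with block-jackknife
    differences pooled by inverse-variance weighting. A synthetic-data module
    generates genotype panels and correlated binary component endorsements
    under a multivariate liability-threshold model, plus an independent
    external cohort's GWAS summary statistics, so the full pipeline is
    testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
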