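Package: snpsetarch
Title: SNP-Set Biclustering and Genotype-Phenotype Architecture for Comorbid Diseases
Version: 0.1.0
Authors@R:
    person("Comorbidity", "Genetics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes a case-control genotype matrix into fuzzy SNP-by-subject
    biclusters with nonsmooth nonnegative matrix factorization (nsNMF), tests each
    SNP set's joint association with two binary diseases using a kernel score test
    with mixture-of-chi-square p-values, relates retained sets to disease-pattern
    subgroups (comorbid, first disease only, second disease only, neither) by
    hypergeometric co-clustering with Jaccard redundancy filtering, and organizes
    the sets into a genotypic network. Includes quality-control and per-SNP
    logistic prescreen stages, readers and writers for dosage TSV, PLINK ped/map
    and VCF, and a synthetic cohort generator with planted biclusters and known
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
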