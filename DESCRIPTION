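Package: cagtools
Title: Continental Ancestry Groups: Supervised Admixture, Structure and
    Differentiation
Version: 0.1.0
Authors@R:
    person("CAG", "Tools Developers", email = "cagtools@example.org",
           role = c("aut", "cre"))
Description: Assigns individuals in a genotyped cohort to continental
    ancestry groups by supervised admixture against reference-population
    allele frequencies, then characterises structure within each group by
    Patterson-normalised principal components with sample projection and
    iterative outlier removal, silhouette-selected K-means clustering,
    correspondence analysis of clusters against place-of-birth labels, and
    pairwise Hudson Fst. Includes windowed LD pruning, genomic-relationship
    based unrelated-subset selection, GT-only VCF and PLINK text input and
    output, and a Balding-Nichols synthetic cohort generator with known
    ancestry, relatedness and birth-place truth so the whole pipeline can be
    exercised without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
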