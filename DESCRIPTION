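Package: epi2d
Title: Detection of Epistatic Locus Pairs Controlling Gene Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide detection of "Epistasis-2D" modules: pairs of loci
    whose joint genotypes epistatically control the co-expression
    (correlation) pattern of pairs of genes in a haploid biparental cross.
    Implements a conditional bivariate normal model whose correlation
    depends on the joint genotype at two markers, likelihood-ratio model
    selection over all genotype partitions, a closed-form PA (Potential of
    Association) pre-filter, 1D-trait (single-gene eQTL) filtering with the
    Wilcoxon rank-sum test, permutation-based false discovery rate
    estimation, and downstream analyses (marker merging, epistasis-map
    clustering, hypergeometric enrichment for function pairs and
    chromosomal intervals).  Includes a synthetic-data generator emulating
    a segregant panel with planted epistatic modules, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
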