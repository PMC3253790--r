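Package: rootgraft
Title: Partitioned Maximum-Likelihood Phylogenetics and Outgroup
    Root-Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitioned maximum-likelihood phylogenetics for mixed
    amino-acid and nucleotide supermatrices (WAG and GTR substitution
    models with discrete-gamma rate heterogeneity), with the
    resampling machinery needed to interrogate the position of a root
    inferred by outgroup attachment: per-site log-likelihoods by
    Felsenstein pruning, nonparametric bootstrap supports, RELL-based
    Shimodaira-Hasegawa and approximately unbiased topology tests, an
    outgroup root-grafting scan over candidate ingroup branches,
    stepwise removal of long-branch outgroup taxa, and a random
    taxon-exclusion experiment that tallies how the inferred root
    moves as taxon sampling shrinks.  A sequence simulator generates
    partitioned alignments along known rooted trees, including the
    long-branch outgroup plus fast-evolving ingroup clade regime in
    which outgroup rooting is prone to long-branch attraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
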