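Package: degenphy
Title: Diagnosing and Filtering Synonymous-Site Compositional Heterogeneity
    in Multi-Gene Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing and filtering among-taxon base-compositional
    heterogeneity at synonymous sites in multi-gene protein-coding data sets.
    Builds codon supermatrices with taxon-by-gene sampling designs, recodes
    characters (degen1 full synonymous degeneration, codon-position subsets,
    the noLRall1+nt2 versus LRall1+nt3 partition, amino acids), runs
    chi-square tests of compositional homogeneity, compares neighbor-joining
    trees from GTR maximum-likelihood and Euclidean compositional distances
    with bootstrap support, evaluates site log-likelihoods under GTR+G+I by
    the pruning algorithm, and performs the approximately unbiased (AU)
    topology test by multiscale RELL bootstrap. A two-layer codon simulator
    with lineage-specific GC3 targets provides ground-truth benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
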