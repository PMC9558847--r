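Package: pseudoortho
Title: Pseudoorthologs and Species Tree Estimation After Whole-Genome
    Duplication
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the formation of pseudoorthologs by differential loss
    of paralogs following a whole-genome duplication (WGD), and measures
    the consequences for species tree estimation. Provides the coalescent
    plus gene-loss distribution of single-copy gene trees (the mixture
    over the eight pruned paralog subtrees), simulation of gene trees
    under the multispecies coalescent on a duplicated species tree,
    fourteen procedural gene-loss patterns, JC69 sequence simulation,
    exact exhaustive maximum-likelihood gene tree estimation at small
    taxon counts, and exact small-scale implementations of five species
    tree methods (STAR, quartet-score maximization, MP-EST
    pseudo-likelihood, concatenated parsimony, and concatenated maximum
    likelihood), together with an experiment driver that compares the
    methods under combinations of species tree, loss pattern, and gene
    count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
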