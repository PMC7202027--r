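Package: phyloscreen
Title: Convergence, Positive Selection and Lineage-Specific Substitution
    Screens on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution screens for protein-coding
    gene sets on a fixed species phylogeny. Implements empirical amino-acid
    (JTT family) and Goldman-Yang codon substitution models, Felsenstein
    pruning likelihoods with marginal (empirical Bayes) ancestral sequence
    reconstruction, detection and model-based testing of convergent and
    parallel amino-acid substitutions between branch pairs (expected-count
    nulls, Poisson and Poisson-binomial tail tests, and a genome-wide
    divergence regression null), branch-site codon likelihood-ratio tests
    for positive selection with FDR control, free-ratio dN/dS estimation,
    fourfold-degenerate site extraction, lineage-specific substitution
    screening with a conservation-based impact score, and a seeded
    sequence-evolution simulator for generating ortholog-set fixtures with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
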