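Package: otukit
Title: Integrated Analysis of Microbiome Census Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated container and toolkit for microbiome census
    (OTU-clustered marker-gene survey) data. Couples an abundance table with
    sample covariates, taxonomy, a phylogenetic tree and reference sequences
    under consistent subsetting semantics; imports BIOM v1 JSON, QIIME legacy
    and mothur tables, Newick trees and FASTA sequences; computes more than 40
    ecological distances including a native Fast UniFrac (weighted and
    unweighted); performs ordination (CA, PCoA, NMDS, PCA, RDA, CCA, DPCoA);
    estimates alpha diversity; controls the family-wise error rate of
    taxon-wise tests with Westfall-Young step-down minP permutations; and
    computes the deterministic data layouts behind the six standard microbiome
    visualisations. A synthetic-data generator and a command-line interface
    over serialised experiment bundles are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    Biostrings,
    igraph,
    phangorn,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    biomformat
Config/testthat/edition: 3
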