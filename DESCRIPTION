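Package: phylogeodiv
Title: Phylogeographic Diversity Analysis for Haplotype Collections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the phylogeography and phylogenetic
    diversity of strain collections genotyped at a single locus. From an
    aligned haplotype set, a rooted gene tree, a site metadata table and a
    strain-to-site mapping, the package derives patristic-distance OTUs,
    per-site alpha phylodiversity (Faith's PD, NRI/NTI with permutation
    nulls, mean root distance), beta-diversity distance matrices (UniFrac,
    Bray-Curtis) with distance-decay tests (Mantel, PERMANOVA), bipartite
    OTU-sharing networks classified by glaciation history, and
    statistical-parsimony haplotype networks with nested clade analysis.
    A synthetic-data generator produces panmixia, founder-style range
    expansion, and phylogenetically clustered scenarios with known ground
    truth so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    vegan,
    igraph,
    geosphere,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'synthetic.R'
    'otu.R'
    'alpha.R'
    'beta.R'
    'haplonet.R'
    'nca.R'
    'sharenet.R'
    'pipeline.R'
    'phylogeodiv-package.R'
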