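Package: gcfkit
Title: Gene Cluster Family Networking and Precursor Mass Bookkeeping for
    Fungal Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups fungal biosynthetic gene clusters (BGCs) into gene
    cluster families using a weighted combination of median backbone-domain
    sequence identity and protein-domain Jaccard similarity, followed by
    density-based (DBSCAN) family calling and UPGMA dendrograms. Also
    provides profile-HMM hit filtering for mining enzyme families such as
    indoleamine 2,3-dioxygenases (Pfam PF01231) across genomes, extraction
    of adenylation-domain substrate-specificity codes against a reference
    synthetase, monoisotopic mass and adduct m/z computation, and nominal
    and exact mass-shift bookkeeping for stable-isotope precursor feeding
    experiments. Includes a synthetic-data generator that emulates families
    of clusters with controlled backbone identity and domain-set overlap so
    the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
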