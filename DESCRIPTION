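Package: smgctools
Title: Prediction, Comparison and Family Analysis of Fungal Secondary
    Metabolite Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts secondary-metabolite gene clusters (SMGCs) in annotated
    fungal genomes from gene coordinates and PFAM domain content, following a
    SMURF-style backbone classification into seven classes (PKS, PKS-like,
    NRPS, NRPS-like, hybrid PKS-NRPS, prenyltransferase, terpene cyclase).
    Scores cluster pairs by a weighted combination of backbone and tailoring
    enzyme percent identities, collapses the resulting weighted network into
    cluster families by random-walk community detection, dereplicates families
    against characterized MIBiG GenBank records, and builds
    best-bidirectional-hit ortholog groups with monocore selection and
    concatenation for downstream phylogenomics. Includes a synthetic pangenome
    generator that plants homologous cluster families at controlled protein
    identity so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
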