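Package: hsg16S
Title: Species-Level 16S rRNA Taxonomic Assignment with Homologous Species Groups
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for species-level profiling of 16S rRNA amplicon data.
    Re-annotates heterogeneous reference lineages against a canonical
    NCBI-taxdump-style taxonomy, extracts hypervariable regions by
    degenerate-primer matching, builds per-species consensus models and
    homologous species groups (connected components of the >=99 percent
    identity graph of species consensus sequences), trains an RDP-style
    naive Bayesian 8-mer genus classifier with bootstrap confidence,
    clusters merged reads into OTUs at a fixed identity threshold, and
    assigns species (or indistinguishable-group) labels to OTU
    representatives by nearest-neighbour search. Ships a synthetic-data
    generator (toy taxonomies, references with planted homologous groups,
    rank-abundance communities, error-bearing amplicon reads) so the whole
    pipeline runs and is tested without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    igraph,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
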