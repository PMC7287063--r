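Package: symbiophylo
Title: Host-Symbiont Metagenome Deconvolution and Gene Provenance Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simple host-symbiont metagenome co-assemblies:
    separating contigs into host and symbiont bins from GC content (two-component
    mixture model) combined with last-common-ancestor taxonomic annotation;
    classifying the evolutionary origin of each gene from ranked non-redundant
    homology hits, including horizontal gene transfer (HGT) candidates, chimeric
    genes and lineage-specific genes; verifying HGT candidates and screening for
    alpha-proteobacterial commensals with explicit gene-tree topology rules;
    selecting conserved phylogenetic markers and building trimmed, partitioned
    supermatrices; and comparing protein-domain repertoires across genomes.
    A seeded synthetic-data generator plants ground truth for every stage so the
    whole pipeline can be exercised and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
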