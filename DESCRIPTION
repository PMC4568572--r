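Package: ipactools
Title: Discovery and Classification of Intergenic Poly(A) Site Clusters
Version: 0.1.0
Authors@R: person("ipactools", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A genome-wide pipeline for characterising polyadenylation events
    that fall outside annotated gene models. Cleavage sites derived from
    poly(A)-tag sequencing are clustered into poly(A) site clusters (PACs),
    annotated against an extended genome annotation, and the intergenic subset
    (IPACs) is classified into 3'-UTR extensions (SE), antisense events (A)
    and orphan sites (SO) using distance-based empirical false discovery rates
    estimated from random intergenic background positions. Additional stages
    profile nucleotide composition and poly(A) signal hexamers around cleavage
    sites, recompute 3'-UTR length distributions after recruiting SE sites,
    cluster orphan sites into candidate novel transcripts, associate them with
    external evidence intervals, and compare IPAC repertoires across samples.
    A synthetic-data module generates annotated toy genomes with planted,
    labelled site classes so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
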