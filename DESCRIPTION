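Package: upominer
Title: Motif-Grammar Mining and Classification of Fungal Unspecific Peroxygenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale genome-mining pipeline for fungal heme-thiolate
    peroxidases. Screens translated proteomes for candidates homologous to a
    query peroxygenase using Smith-Waterman local alignment with
    Karlin-Altschul E-value statistics, reduces redundancy by greedy identity
    clustering, refines the candidate set by Markov clustering of the
    similarity graph, validates candidates against the conserved catalytic
    motif grammar of unspecific peroxygenases (UPOs) and chloroperoxidases
    (CPOs), and classifies validated sequences into five UPO subfamilies, the
    peroxidase-peroxygenase (Pog) superfamily, or classic CPOs. Includes a
    neighbor-joining tree stage for superfamily placement and a seeded
    synthetic-proteome generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
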