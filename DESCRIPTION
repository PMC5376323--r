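Package: chemgroups
Title: Chemical-Group Reduced-Alphabet Characterization of Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free characterization of protein sequences through a
    reduced alphabet of eight amino acid chemical groups (acidic, basic,
    aromatic, aliphatic, cyclic, sulfur-containing, hydroxyl-containing and
    acidic amide). Provides group-composition vectors and an L1
    percent-composition dissimilarity between sequences, single-linkage
    dendrograms built from the dissimilarity matrix with Newick export,
    order-pair directed graphs whose edges are consecutive group transitions,
    bounded-length simple-cycle enumeration with group-unique cycle contrasts
    and subdomain window mapping, chemically conserved k-mer and pattern
    search with mismatch tolerance, and a seeded generator of sequences with
    controlled group composition. Ships the worked cytochrome c7 (PpcA-E)
    composition tables as plain-text fixtures and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
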