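Package: cdguide
Title: C/D Box sRNA Annotation and rRNA 2'-O-Methylation Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates archaeal C/D box small RNAs (C, D', C' and D box motifs,
    kink-turn plausibility, guide regions), predicts ribose 2'-O-methylation
    targets in 16S and 23S ribosomal RNA by bulge-free antiparallel guide-target
    duplex scanning under the N-plus-five rule, and maps predictions onto
    multi-species rRNA alignments to profile site conservation, methylation
    hotspots, within-species target redundancy and distant-target (RNA chaperone
    candidate) small RNAs. Ships a seeded synthetic-data generator with planted
    ground truth so every pipeline stage can be validated end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
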