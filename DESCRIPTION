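Package: pbtrkit
Title: In Silico Golden Gate Cloning with the pBTR Binary Vector System
Version: 0.1.0
Authors@R:
    person("pbtrkit", "developers", email = "pbtrkit@example.org", role = c("aut", "cre"))
Description: Tools to plan and simulate Golden Gate cloning into the pBTR
    series of plant binary expression vectors. The package models type-IIS
    (BsaI) restriction-site discovery and digestion into sticky-ended
    fragments on linear and circular molecules, enumerates circular ligation
    products of the one-pot one-way digestion-ligation reaction (including
    inserts that carry internal BsaI sites and multiplexed reactions),
    designs adapter-tailed primers for every vector in the built-in pBTR
    registry, predicts recombinant plasmid sequences, E. coli colony colour
    from the PnptII::mScarlet-I screening cassette, and restriction-map
    screening outcomes. A synthetic-fragment generator produces test inputs
    with controlled internal-site architectures so the whole toolkit runs
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
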