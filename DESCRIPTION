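Package: httdetect
Title: Detection and Dating of Horizontal Transposon Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and date horizontal transfer of transposable
    elements (HTT) between host lineages. Reconstructs consensus sequences of
    Tc1/Mariner-like element families from copy alignments and annotates their
    anatomy (terminal inverted repeats, TA target-site duplications, longest
    transposase ORF); computes Jukes-Cantor corrected distances with pairwise
    deletion; tests transposon distances between taxa against the
    vertical-inheritance null given by orthologous gene distances; dates
    amplification bursts from mean copy-to-consensus divergence and a neutral
    substitution rate; and quantifies host/element tree discordance through
    neighbor-joining copy trees, per-species copy monophyly, Dollo-parsimony
    loss counts, and Robinson-Foulds distances. A sequence simulator generates
    host trees, purifying-selection gene alignments, and neutrally evolving
    element copies with explicit vertical or horizontal transfer histories so
    the whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
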