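Package: nucpatterns
Title: Dyad-Aligned Sequence Patterns and Positioning of Nucleosome Populations
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the DNA sequence organisation of nucleosome
    core particles from mapped nucleosome-sized fragments. Computes
    dyad-aligned positional frequency profiles of mononucleotides (A, T,
    W = A/T) and dinucleotide classes (WW, SS) with 3-bp running averages and
    dyad symmetrisation, differential (delta-W) profiles between two
    nucleosome populations with baseline statistics and position-wise
    significance testing, inter-population distance cross-correlation (DCC)
    of dyad maps with peak calling and in-phase (10n) versus counterphase
    (10n+5) partitioning, and a phase-correlation classifier separating
    canonical WW/SS from anti-WW/SS rotational settings. A synthetic fragment
    generator with planted periodic composition, off-peak enrichments, strand
    asymmetry and inter-population dyad shifts provides ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    tools,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
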