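Package: coiprofile
Title: COI Barcode Profiles for Distance-Based Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for DNA-barcode species identification from aligned
    mitochondrial COI fragments: pairwise Kimura two-parameter (K2P)
    divergences with pairwise or complete deletion, neighbor-joining
    similarity profiles with deterministic tie-breaking, partitioning of
    divergences into intraspecific and interspecific sets with tabular and
    histogram summaries, alignment site statistics (constant, variable,
    parsimony-informative), tree-based cohesion diagnostics with
    cryptic-species and synonymy candidate flags, and a Kimura
    two-parameter sequence simulator that generates alignments with full
    ground truth for pipeline validation.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
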