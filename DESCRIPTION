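Package: crownsim
Title: Crown-Group Emergence Times in Birth-Death Phylogenies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates constant-rate birth-death phylogenies over a fixed
    duration, conditions on survival to the present by rejection, and
    measures when the crown group (the clade of the most recent common
    ancestor of all extant lineages) emerges relative to the origin of its
    total group.  Provides the two classical parameter sweeps over equal
    speciation/extinction rates and over positive diversification rates,
    time-calibrated Newick import/export with extinct/extant tip flags,
    hand-built fixture trees with known crown nodes, and a brute-force
    MRCA oracle for validating the crown-finding code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
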