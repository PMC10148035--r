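Package: caulopolar
Title: Spatiotemporal Turing-Pattern Model of Cell Polarity in Caulobacter crescentus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the establishment of cell polarity over the cell cycle of
    Caulobacter crescentus. Three self-assembling scaffolding proteins (PopZ,
    PodJ, SpmX) polymerize by an activator-substrate-depletion (Turing)
    reaction-diffusion mechanism on a growing, dividing one-dimensional cell,
    and recruit the DivJ/PleC-DivK and DivL-CckA-CpdR/CtrA phosphorelay
    modules that set the asymmetric distribution of phosphorylated CtrA
    between the swarmer and stalked daughter cells. Includes discrete
    cell-cycle event logic (replication initiation by a CtrA~P threshold,
    fork-passage methylation switching, Z-ring closure, division), a
    declarative mutant-strain catalog, kymograph export, synthetic
    pseudo-experimental data generation, and two-objective evolutionary
    calibration of the free parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
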