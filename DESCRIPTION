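Package: dnatwist
Title: Torsional Dynamics of Double-Stranded DNA as Coupled Base Pendulums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the rotational motion of nitrogenous bases around the
    sugar-phosphate backbone of a double-stranded DNA molecule, modelled as two
    coupled chains of pendulums with elastic inter-chain (hydrogen-bond) links,
    viscous dissipation, and a spatially uniform periodic driving torque. The
    Cauchy problem for the 2n coupled Newton equations is solved with a
    fixed-step classical Runge-Kutta 4 integrator (compiled core). An analysis
    layer extracts the chain-mean angular deviation, its post-transient
    amplitude and dominant frequency, and a time-resolved frequency track, and
    an experiment harness runs drive-frequency sweeps and homopolymer
    block-substitution comparisons on real (FASTA) or seeded synthetic
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
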