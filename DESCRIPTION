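Package: patternet
Title: Deep-Learning Interpretation of Crystallographic Patterson Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bypassing the crystallographic phase problem on small
    peptide structures with a convolutional neural network. Generates paired
    Patterson-map / electron-density volumes for dipeptides (from PDB files or
    a built-in synthetic conformer generator), computes structure factors and
    periodic map syntheses from first principles, trains a 3D residual U-net
    that maps normalized Patterson maps to electron densities, and evaluates
    predictions by Pearson correlation and amplitude-weighted phase error per
    resolution shell. Includes CCP4/MRC map input/output and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
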