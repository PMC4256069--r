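Package: gasmap
Title: Implicit Ligand Sampling Maps and Gas-Migration Pathway Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locates gas-migration channels in fluctuating molecular
    matrices. Computes three-dimensional free-energy maps for a small
    apolar diatomic probe by Widom-style test-particle insertion into a
    conformational ensemble (implicit ligand sampling), converts maps
    between vacuum and water references, builds probability-density
    grids from explicit-ligand trajectories, and analyses free-energy
    landscapes into basins, saddle points, pathway networks and channel
    profiles with block-based error estimates. Includes generators for
    synthetic fluctuating cavity/channel systems with known ground
    truth, OpenDX grid input/output and Kabsch superposition of
    ensemble frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
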