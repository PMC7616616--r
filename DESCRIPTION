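Package: selfnav3d
Title: Self-Navigated 3D Multi-Slab Diffusion MRI Sampling Design and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for navigator-free ("self-navigated") 3D multi-slab
    diffusion MRI. Designs extended-CAIPI multi-shot EPI sampling patterns in
    which every shot intersects the central kz plane, optimises the multi-shot
    pattern by greedy search over overlap, k-space gap and self-navigation
    metrics, estimates a 2D motion-induced phase map per shot from the central
    plane intersections with a SPIRiT-regularised structured low-rank (block
    Hankel) ADMM reconstruction, and performs the phase-corrected multi-shot
    SPIRiT reconstruction of the slab. A synthetic-data module generates
    phantom slabs, band-limited coil sensitivities, shot-wise phase errors and
    noisy under-sampled multi-coil k-space so the full pipeline can be
    exercised and benchmarked without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
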