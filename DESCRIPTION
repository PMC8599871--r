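Package: bldna
Title: Two-Phase Worm-Like-Chain Analysis of the B-to-L Transition in
    Negatively Supercoiled DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses magnetic-tweezers extension-versus-turns
    experiments on torsionally constrained DNA held under mild tension while
    being unwound.  Implements the classical worm-like-chain (WLC)
    force-extension relation and its numerical inverse, a two-phase (B-form /
    L-form) mixture model in which the L-DNA fraction grows linearly with
    imposed negative turns, the resulting inversion force at which the mixed
    phase extension becomes independent of twist, and the inverse inference of
    L-form mechanical parameters (persistence length, rise per base pair) from
    a measured inversion force.  Includes a geometric backbone-conservation
    derivation of the L-to-B contour-length ratio, a simplified plectoneme
    slope surrogate, a seeded synthetic-trace generator emulating
    magnetic-tweezers data, and a segmentation/slope-fitting pipeline that
    recovers the inversion force and L-form persistence length from traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
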