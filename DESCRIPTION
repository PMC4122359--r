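Package: relaxfit
Title: Backbone 15N Relaxation Analysis and Lipari-Szabo Model-Free Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein backbone 15N relaxation data:
    single-exponential fitting of peak-intensity decays into R1 and R2 rates
    with Monte-Carlo uncertainties, steady-state heteronuclear NOE computation,
    reduced spectral density mapping (J(0), J(wN), J(0.87wH)), rotational
    diffusion tensor estimation (isotropic and axially symmetric) from R2/R1
    ratios with F-test model selection, per-residue Lipari-Szabo model-free
    fits over the standard five-model ladder with staged statistical model
    selection, amide chemical-shift-perturbation mapping between apo and holo
    peak lists, and coordinate utilities (NH-vector extraction, Kabsch
    superposition, per-residue value maps). A seeded synthetic-data generator
    emulating a monomeric flavodoxin-like protein produces every input the
    pipeline consumes, so all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
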