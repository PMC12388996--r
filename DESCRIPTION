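Package: liporelax
Title: NMR Relaxometry and Quality Control for Liposomal Nanoformulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cationic liposomal co-formulations
    characterized by proton NMR relaxometry and colloidal quality control.
    Fits single-exponential saturation-recovery curves (spin-lattice T1) and
    two-component Gaussian plus Lorentzian transverse decays (spin-spin T2),
    models the off-resonance rotating-frame equilibrium magnetization ratio,
    estimates the relaxation enhancement factor K and inverts it for the
    rotational correlation time, screens dynamic light scattering size/PDI and
    zeta-potential tables against injectability criteria, computes
    encapsulation efficiency, and estimates IC50 from MTT dose-response data
    by logistic fitting. Includes seeded synthetic-data generators for every
    input so the full pipeline is testable without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
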