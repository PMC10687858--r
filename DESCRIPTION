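Package: neoscf
Title: Nuclear-Electronic Orbital Hartree-Fock with Local Density Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multicomponent self-consistent field calculations in which
    selected protons are treated quantum mechanically on the same footing as
    the electrons (nuclear-electronic orbital restricted Hartree-Fock,
    NEO-RHF). Provides a contracted-Gaussian integral engine
    (McMurchie-Davidson), robust density fitting for all Coulomb and exchange
    builds, local-domain exchange fitting based on intrinsic bond orbitals, a
    block-diagonal nuclear starting guess, a stepwise nuclear/electronic
    macro-iteration driver with DIIS, cube-file export of proton densities,
    and a composite correction that adds nuclear quantum effects to any
    electronic-structure energy.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
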