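Package: pbwave
Title: Exact Travelling-Wave Solutions and Dynamics of the Continuum
    Peyrard-Bishop DNA Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A verifiable workbench for the continuum Peyrard-Bishop model of
    DNA base-pair opening. Re-derives the model's travelling-wave solution
    families (solitary, soliton, elliptic, periodic-rational and
    soliton-rational) with an exact polynomial elimination engine implementing
    the unified ansatz method, verifies every branch by symbolic
    back-substitution and by the residual of the governing PDE, computes the
    modulation-instability dispersion relation and gain spectrum, and
    propagates solutions numerically with a method-of-lines RK4 integrator
    with conservation and convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
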