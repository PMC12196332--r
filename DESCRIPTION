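Package: fesgpr
Title: Free Energy Surface Reconstruction from Metadynamics Gradients by
    Gaussian Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing one-dimensional free energy surfaces
    along a collective variable, built around ion-pairing potentials of mean
    force. Provides a synthetic double-well generator with exact gradients and
    a Langevin sampler, a well-tempered metadynamics engine (tempered hill
    deposition, bias evaluation, scaled-bias free energy estimates), gradient
    unbiasing of biased trajectory frames into free-energy-derivative training
    data, Gaussian process regression on derivative observations with dense
    and inducing-point (grid-sparsified) solvers, an umbrella-sampling WHAM
    reference pipeline, and an evaluation layer with error norms, landmark
    localization and hyperparameter sweeps. File formats interoperate with
    PLUMED HILLS/COLVAR and Grossfield WHAM conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
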