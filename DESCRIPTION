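Package: rwmanifold
Title: Reweighted Manifold Learning from Enhanced-Sampling Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Manifold learning for collective-variable discovery from biased
    (enhanced-sampling) molecular simulation data. Provides diffusion
    reweighting, a pairwise reweighting factor that unbiases Markov transition
    matrices built from well-tempered metadynamics trajectories, together with
    reweighted anisotropic diffusion maps, the stochastic embedding methods
    mrse and stke trained by Kullback-Leibler divergence minimization, and a
    self-contained Langevin/well-tempered-metadynamics engine on analytic
    multi-well potentials for generating biased training data. Reads and
    writes PLUMED-style COLVAR and HILLS files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
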