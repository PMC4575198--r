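Package: hdpslds
Title: Trajectory Segmentation and Force Inference for Single-Particle
    Tracking via Sticky HDP Switching Linear Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments noisy two-dimensional single-particle tracking
    trajectories into an unknown number of latent linear-dynamical states
    using a truncated sticky hierarchical Dirichlet process (HDP) blocked
    Gibbs sampler, refines per-segment dynamical parameters by maximum
    likelihood with exact Kalman-filter likelihoods, tests model adequacy
    with a kernel-based goodness-of-fit statistic on probability integral
    transform residuals, and converts fitted linear stochastic dynamics
    into instantaneous effective force vectors and restoring-force
    eigen-structure through the overdamped Langevin model and the Einstein
    relation.  Includes a switching linear dynamical system simulator
    emulating common measurement artifacts (localization-noise ramps,
    periodic outlier frames, rapid state switching) and segmentation
    scoring metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
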