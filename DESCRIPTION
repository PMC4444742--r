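Package: kinencode
Title: Kinematic Encoding Analysis of Substantia Nigra Single-Unit Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links single-unit firing in the substantia nigra to movement
    kinematics measured by 2D video tracking. Decomposes head-position
    trajectories into eight rectified directional velocity and acceleration
    components, classifies units by a two-step lag-optimized
    cross-correlation against each component (best-lag search followed by a
    shifted Pearson correlation with significance testing), and computes
    population-level statistics: class tabulation, direction opponency,
    hemispheric lateralization, valence comparisons, firing-rate and
    lag-asymmetry tests, and two-way ANOVA of optogenetic stimulation
    kinematics. Includes a synthetic-session generator built on a
    hierarchical cascade (velocity-over-position) negative-feedback control
    model with a leaky-integrator stage and a multiplicative dopamine gain,
    plus inhomogeneous-Poisson tuned units, so every analysis stage can be
    validated by ground-truth parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
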