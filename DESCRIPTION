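Package: affinet
Title: Quantitative Protein-Interactome Affinity Pipeline for Live-Cell FCCS,
    DULIP and Reporter Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying binary protein-protein interactions of a
    transcription factor hub (NRF2/NFE2L2) across complementary assay
    platforms and assembling the evidence into an affinity-weighted binary
    interaction network. Implements analytic fluorescence (cross-)correlation
    spectroscopy models with two-component diffusion and triplet correction, a
    multi-tau correlator for photon-count traces, Levenberg-Marquardt curve
    fitting, conversion of correlation amplitudes to molar concentrations and
    bound fractions, binding-isotherm dissociation-constant estimation with
    bootstrap confidence intervals, dual-luminescence co-immunoprecipitation
    (DULIP) interaction-ratio quantification with cross-platform scaling to
    molar units, a profiled-REML random-intercept linear mixed model with
    Satterthwaite contrasts for ARE-luciferase reporter screens, yeast
    two-hybrid matrix scoring, and GraphML/SIF network export. A synthetic-data
    module generates ground-truth-known inputs (binding equilibria, correlation
    curves, Brownian-dynamics photon traces, DULIP wells, reporter plates, Y2H
    call matrices) so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest
Config/testthat/edition: 3
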