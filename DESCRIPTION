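Package: ptscreen
Title: Goodness-of-Fit Screening and Diffusion Metrics for Particle-Tracking
    MSD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiple-particle-tracking experiments in viscous
    biological media such as intestinal mucus. Fits each particle's mean
    squared displacement (MSD) versus lag time to the anomalous diffusion
    model MSD = 4*D*tau^alpha by log-linear or bounded non-linear least
    squares, computes goodness-of-fit diagnostics (R2, RSS, RMSE) in
    untransformed MSD space, and screens trajectories either by the
    conventional R2 threshold or by a combined R2/RSS decision rule that
    keeps well-fitting and mucus-trapped (flat, low-residual) particles while
    discarding erratic ones. Derives per-particle and population diffusion
    metrics: ratios to a reference medium, the diffusivity factor
    D_long/D_short, anomalous-exponent transport classes, prototype (median)
    particles, mean/median heterogeneity ratios, and first-passage times
    across a mucus layer. A seeded simulator of power-law MSD curves,
    fractional Brownian tracks, and labelled diffusive/adhesive/erratic
    mixtures makes every stage reproducible without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
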