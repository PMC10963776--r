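Package: firebias
Title: Stochastic Simulation of the Wildfire Suppression Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thousands of independent wildfires under identical
    biophysical conditions that differ only in their suppression scenario, to
    quantify how differential ("regressive" or "progressive") fire suppression
    biases realized fire severity, burned-area growth, and the diversity of
    fire effects across fuel-aridity and fuel-loading gradients. Includes a
    seeded fire-season weather generator (Weibull winds, temporally
    autocorrelated fuel moistures driven by vapor pressure deficit), a
    Rothermel-based surface and crown fire behavior core, Huygens-style
    elliptical fire growth with per-angle perimeter tracking, a two-stage
    suppression filter (stochastic initial attack plus intensity-dependent
    daily containment), flame-length-to-Composite-Burn-Index severity mapping,
    and regime summaries (Lorenz curves, growth rates, doubling times,
    years-equivalent conversions, replicate confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
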