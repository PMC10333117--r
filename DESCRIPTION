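Package: nicetrends
Title: Neutral Baselines and Colonization-Extinction Imbalance for
    Biodiversity Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether trends in species richness estimated from
    finite, temporally autocorrelated community time series deviate from a
    neutral expectation.  Implements a two-state Markov (island biogeography)
    simulator of presence-absence dynamics with known equilibrium richness and
    lag-1 autocorrelation, optimal linear estimation (OLE) of per-species
    colonization and extinction times with window censoring, the NICE
    statistic (net imbalance between cumulative colonizations and
    extinctions), chronosequence-randomization null models, per-series and
    mixed-effects richness-trend estimators, and a heteroscedastic normal
    maximum-likelihood model for the effect of series length on trend
    estimates.  Includes synthetic-data generators that emulate fish- and
    bird-survey style collections and directional change scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
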