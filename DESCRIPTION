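Package: isobud
Title: Stable Water Isotope Labelling and Phenology Analysis of Tree Bud Dormancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying winter bud dormancy in temperate deciduous
    trees from twig-cutting assays. Implements deuterium-labelling arithmetic
    (natural-abundance background lines, delta to atom-percent conversion,
    excess-label short-term water uptake), bud water content from fresh and
    dry masses, budburst success and thermal time to budburst under constant
    forcing, daily climate aggregation and frost-date detection from hourly
    temperature loggers, endodormancy-onset change-point detection on uptake
    trajectories, mixed-effects models of the four dormancy responses with
    type II/III ANOVA and Tukey post-hoc contrasts, campaign-filtered
    species-specific Pearson correlations, and a synthetic-data generator that
    emulates a two-site, five-species, multi-campaign labelling experiment for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmmTMB,
    car,
    emmeans,
    sandwich,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
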