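Package: tbwave
Title: Phase Partitioning and Shape Analysis of Body Temperature Distributions
Version: 0.1.0
Authors@R:
    person("Core", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing frequency distributions of continuous core
    body temperature recordings from endotherms. Fits penalized additive
    quantile-regression curves over time (a non-stationary waveform analysis)
    at the 45th and 55th quantile levels, classifies every reading as active,
    resting or transitional relative to those curves, and characterizes the
    resulting distributions by kernel-density modal temperature, 10th/90th
    quantiles, skewness with bootstrap direction classification, and
    Hartigan's dip test for bimodality. Includes a seeded synthetic trace
    generator emulating homeothermic, heterothermic, torpor-using and
    heat-storing thermoregulatory phenotypes with ground-truth phase labels,
    per-individual summaries (including the daily amplitude between active
    and resting modes), cross-individual panel statistics, and a scripted
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
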