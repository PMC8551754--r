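# tbwave

Analysis of core body-temperature frequency distributions from implanted
loggers in endotherms.

Most endotherms are not strict homeotherms: body temperature cycles daily
between an active-phase plateau and a lower resting plateau, drifts
seasonally, and in many species dips steeply during torpor or spikes with
activity. Comparative physiologists increasingly summarise such telemetry
not by a mean but by the *shape* of the body-temperature distribution —
separately for the active and rest phases of the daily cycle. `tbwave`
implements that analysis as a tested, reusable pipeline:

1. **Waveform phase split.** Two penalized additive quantile-regression
   curves are fitted over time at levels τ = 0.45 and τ = 0.55, minimising
   the pinball (check) loss ρ_τ(u) = u(τ − 1\{u<0\}) plus an L1 roughness
   penalty on the spline coefficients, solved as an exact linear program
   by an interior-point method. Because interior knots are at least 48 h
   apart (two daily periods), the curves can track slow changes in the
   *level* of the cycle — seasonal drift, oestrus — but not the cycle
   itself. Readings strictly above the 55th-quantile curve are classified
   ACTIVE, strictly below the 45th REST, and the band in between
   TRANSITIONAL. The split uses no clock time and no absolute temperature
   threshold.
2. **Distribution shape.** For the active, rest and overall reading sets:
   the modal temperature (Gaussian-KDE argmax, Silverman bandwidth, 0.01 °C
   grid), the 10th/90th quantiles, moment skewness with a bootstrap
   direction call (left / right / symmetric), and Hartigan's dip test for
   bimodality (own GCM/LCM implementation with a Monte-Carlo uniform-null
   p-value). The daily amplitude is the active mode minus the rest mode.
3. **Panel summaries.** Per-individual summaries aggregate into
   cross-species panels: KDE mode, mean, SD and range of active mode, rest
   mode and amplitude, plus counts of right-/left-skewed and bimodal
   members.
4. **Synthetic data.** A seeded generator produces ground-truth-labelled
   traces — plateau-shaped circadian cycle `mesor + A·tanh(k sin x)/tanh(k)`,
   drift, Gaussian sensor noise, torpor bouts (exponential-approach drops),
   activity-hyperthermia bursts (exponential tails) — so the entire
   pipeline is testable without any telemetry download.

## Worked example

```r
library(tbwave)

# 30 days of synthetic telemetry from a torpor-using small mammal:
# mesor 36.4 degC, plateau half-amplitude 1 degC, 10-min sampling,
# a torpor bout on ~30% of days dropping 8 degC below the rest plateau
cfg <- sim_config(torpor_prob_per_day = 0.3, torpor_depth_c = 8, seed = 42)
tr  <- simulate_trace(cfg)
tr
#> <tb_trace> sp1 / ind1: 4320 readings over 719.8 h (interval 10.0 min)
#>   tb_c: 27.60-37.91 degC (truth labels present)

pt <- partition_trace(tr)          # fit tau = 0.45 / 0.55 curves, classify
pt$partition
#> <tb_phases> active 1944 | rest 1944 | transitional 432

s <- summarize_individual(tr, pt$partition, shape_config(seed = 1))
s
#> <tb_individual_summary> sp1 / ind1
#>   active mode 37.42 | rest mode 35.39 | amplitude 2.03 degC

s$overall
#> <tb_shape_stats> n=4320 mode=37.36 q10=35.22 q90=37.49 skew=-2.543 (left)
#>   dip=0.1139 p=0.001 bimodal=TRUE
```

Reading the output: the partition recovers the generator's plateaus — the
active mode (37.42 °C) and rest mode (35.39 °C) sit at mesor ± amplitude,
so the daily amplitude is ≈ 2 °C. The overall distribution is bimodal
(dip p = 0.001: the two plateaus) and left-skewed (skew −2.5): the torpor
bouts put mass deep into the left tail, the signature this analysis is
designed to expose.

A 14-species demonstration panel with designed shape classes:

```r
panel <- simulate_panel(default_panel_configs(), master_seed = 1)
summaries <- lapply(panel, function(tr) {
  pt <- partition_trace(tr)
  summarize_individual(tr, pt$partition, shape_config(seed = 1))
})
summarize_panel(summaries)   # 8 right-skewed, 8 bimodal by construction
```

## Command line

```sh
inst/cli/tbwave simulate --duration_days 30 --seed 1 --out trace.csv
inst/cli/tbwave fit      --trace trace.csv --out curves.csv
inst/cli/tbwave classify --trace trace.csv --curves curves.csv --out labels.csv
inst/cli/tbwave stats    --labels labels.csv --seed 1 --out stats.json
inst/cli/tbwave run-all  --config run.yaml        # or .json
```

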