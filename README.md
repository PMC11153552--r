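# circalux

Circadian analysis of bioluminescence plate recordings.

`circalux` is for chronobiologists who record luciferase reporter activity
from multi-well plates — populations of *C. elegans* (or other organisms)
whose clock-controlled promoter drives `luc`, read every 30 minutes for a
week on a plate luminometer — and need per-well rhythm phenotypes and
group-level summaries: which wells are rhythmic, with what free-running
period, whether they entrained to the zeitgeber, and how tightly replicate
wells cluster in phase.

## What it computes

Given a plate CSV and a protocol schedule (entrained epochs under a 12:12 h
zeitgeber cycle, free-run epochs under constant conditions), the pipeline:

1. **Preprocesses** each well: background subtraction, removal of the first
   24 h (luciferase accumulation transient), moving-average detrending
   (24-h window), boxcar smoothing (2.5 h), normalization to the initial
   maximum.
2. **Estimates the period** on the free-run epoch with a from-scratch
   classical **Lomb–Scargle periodogram** (variance-normalized, per-frequency
   offset τ) over the circadian band 18–35 h with oversampling 30. At every
   grid frequency the power equals the variance explained by the
   best-fitting sinusoid, P(ω) = ESS(ω) / (2s²).
3. **Classifies rhythmicity by cosinor**: y(t) = M + A·cos(2π(t−φ)/τ),
   fit exactly by linear least squares at fixed τ. A well is
   *Synchronized* if the 24-h fit on the entrained epoch has R² ≥ 0.5, and
   *Circadian* if the fit at the Lomb–Scargle period on the free-run epoch
   has 18 ≤ τ ≤ 35 h and R² ≥ 0.5.
4. **Extracts peak phases** (last entrained day as ZT; first 26 h after
   release) and summarizes them with **circular statistics**: mean phase,
   mean resultant length R, and the Rayleigh uniformity test
   (Z = nR², Zar's approximation), as drawn on Rayleigh plots.
5. **Aggregates per group**: n, % rhythmic, period mean ± SEM over rhythmic
   wells, and circular phase summaries.

A seeded synthetic-plate generator (`simulate_plate()`) emulates the
recordings — multiplicative oscillation on a rising/decaying baseline,
partial rhythmicity, per-well period dispersion, masking transients,
counting noise — so every stage is testable against known ground truth.

## Worked example

```r
library(circalux)

sim <- simulate_plate(default_study_config(seed = 42))  # 2 groups x 30 wells
res <- analyze_recording(sim$recording)
dplyr::select(res, well, group, sync_category, circadian_category,
              fr_period_h, circadian_r_squared)
#> # A tibble: 60 × 6
#>   well  group   sync_category circadian_category fr_period_h circadian_r_squared
#>   <chr> <chr>   <chr>         <chr>                    <dbl>               <dbl>
#> 1 W01   control SYNCHRONIZED  CIRCADIAN                 25.7               0.829
#> 2 W02   control SYNCHRONIZED  CIRCADIAN                 24.4               0.829
#> 3 W03   control SYNCHRONIZED  CIRCADIAN                 23.8               0.864
#> 4 W04   control SYNCHRONIZED  CIRCADIAN                 24.2               0.845
#> # i 56 more rows

summarize_groups(res)[, 1:8]
#>     group n_total n_rhythmic percent_rhythmic period_mean_h period_sem_h ldcw_R   fr_R
#> 1 control      30         19            63.33         24.52       0.2206 0.9647 0.9688
#> 2  mutant      30         16            53.33         26.65       0.3223 0.9747 0.9598
```

Reading the output: of 30 control-like wells, 19 (63%) expressed a
free-running rhythm with mean period 24.52 ± 0.22 h, while the simulated
long-period group came out at 26.65 ± 0.32 h — the generating means were
24.4 and 26.4 h. Entrained peak phases cluster tightly (resultant length
R ≈ 0.96–0.97 on the last zeitgeber day; R = 1 means identical phases,
R near 0 means no phase agreement).

Individual fits are ordinary R objects with `tidy()`/`glance()` methods:

```r
t <- seq(0, 72, 0.5)
fit <- cosinor_fit(data.frame(time_h = t,
                              value = 10 + 3 * cos(2 * pi * (t - 5) / 24)), 24)
fit
#> <cosinor_fit> tau = 24 h | mesor 10, amplitude 3, acrophase 5 h, R^2 = 1.0000 (n = 145)
```

Plots: `autoplot(lomb_scargle(...))` for periodograms,
`plot_rayleigh(phases)` for polar phase plots with the p = 0.05 circle,
`plot_well_traces(rec)` for quick trace QC.

A command-line wrapper is installed with the package
(`system.file("scripts", "circalux", package = "circalux")`) with
subcommands `simulate`, `analyze`, and `report`; see `?run_cli`.

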