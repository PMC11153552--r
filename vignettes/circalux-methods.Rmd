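---
title: "Analysis of circadian bioluminescence plate recordings with circalux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of circadian bioluminescence plate recordings with circalux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalux)
library(dplyr)
```

## The measurement and the questions

Luciferase reporter assays record the transcriptional activity of a clock
output gene as light. A plate luminometer integrates photons from each well —
here a well holds a small population of animals (nominally ~50) in
luminescence medium — every 30 minutes for about a week. A typical protocol
entrains the populations for three days under a 12:12 h zeitgeber cycle
(light–dark combined with a cold–warm temperature cycle) and then releases
them into constant darkness and temperature ("free run", FR) for four days;
constant-only protocols of about seven days are also common. Three questions
are asked of every well:

1. **Is it rhythmic, and with what endogenous period?** (free-run epoch)
2. **Was it synchronized by the zeitgeber?** (entrained epoch)
3. **At what phase does it peak**, and how tightly do replicate wells
   cluster in phase? (both epochs)

`circalux` implements this pipeline end to end: plate CSV + protocol
schedule in, per-well classifications and group summaries out, with a
synthetic-plate generator that provides ground truth for every stage.

## The time axis

All series use decimal hours since the start of the recording. The protocol
schedule — an ordered set of `CYCLIC` / `FREE_RUN` epochs plus
`zt0_recording_offset` — carries the zeitgeber anchoring;
`recording_time_to_zt()` maps recording time to Zeitgeber Time
(ZT0 = lights-on / cold-phase onset) by simple modular arithmetic. Keeping a
single internal axis and treating ZT as a *view* avoids the ambiguity of
mixing ZT, circadian time, and "hours of recording" in one data structure.
Schedules are supplied as JSON metadata, never inferred from the data.

## Preprocessing

Raw counts are transformed in a fixed order:

1. **Background subtraction** — a scalar, or the pooled median of designated
   blank wells. Negative values are retained; clamping would bias later
   stages. When no background information exists, 0 is used (with a warning):
   detrending absorbs constant offsets anyway.
2. **Initial truncation** (default 24 h, configurable; 12–24 h is the
   realistic range) — luciferase accumulates over the first half-day to day
   of recording, producing a large transient with no circadian
   interpretation. Times are *not* re-zeroed, so the schedule stays aligned.
3. **Detrending** (default window 24 h) — subtraction of a centered moving
   average. The window mean is computed as the *integral* (trapezoidal)
   average of the points in `[t - w/2, t + w/2]`: the integral mean of a
   sinusoid over one full matched-period window is exactly zero, so a
   one-cycle window removes the slow baseline decay while passing the
   circadian component untouched. (A discrete point mean leaks a small
   fraction, about 1/N of the oscillation, back into the trend estimate.)
   Windows shrink at the series edges, which leaves small phase-dependent
   envelope residuals there — the practical consequence is quantified below.
4. **Smoothing** (default window 2.5 h = 5 samples at 30-min sampling) — a
   plain centered boxcar over the samples in the window, suppressing
   integration noise while displacing symmetric peaks by less than one
   sample.
5. **Normalization** — division by the maximum over the first 24 h after
   truncation (computed after detrend + smooth). Normalization is cosmetic:
   both the Lomb–Scargle peak location and the cosinor R² are invariant
   under affine transforms of the signal, so this choice only affects
   plotting scales. Whether the original analyses took the "initial maximum"
   before or after detrending is not documented anywhere we know of; taking
   it after guarantees the normalizing constant is positive for any well
   with signal.

Missing readings are kept as gaps and simply dropped from whichever sums
need values; nothing is interpolated or imputed.

## Period estimation: Lomb–Scargle

The endogenous period is estimated with a from-scratch classical
Lomb–Scargle periodogram on the mean-subtracted preprocessed free-run
segment, with the per-frequency offset \(\tau\) defined by
\(\tan(2\omega\tau) = \sum\sin(2\omega t_i)/\sum\cos(2\omega t_i)\) and power

\[
P(\omega) = \frac{1}{2 s^2}\left[
\frac{\left(\sum_i y_i' \cos\omega(t_i-\tau)\right)^2}{\sum_i \cos^2\omega(t_i-\tau)}
+
\frac{\left(\sum_i y_i' \sin\omega(t_i-\tau)\right)^2}{\sum_i \sin^2\omega(t_i-\tau)}
\right],
\]

where \(y' = y - \bar y\) and \(s^2\) is the sample variance
(variance normalization, the convention of the classical chronobiology
toolchain). With this normalization \(P(\omega)\) equals the variance
explained by the best-fitting single sinusoid at \(\omega\) in units of
\(s^2/2\), a fact the test suite exploits: an explicit per-frequency
least-squares regression reproduces every grid value to 10⁻⁸, and on even
sampling the classical DFT periodogram does too.

The search band is 18–35 h — wide enough for strongly long-period clock
mutants, narrow enough to exclude harmonics — with a frequency grid uniform
from 1/35 to 1/18 h⁻¹ at spacing no coarser than \(1/(\text{ofac}\cdot
\text{span})\), ofac = 30. Both band edges are on-grid. `best_period()`
takes the grid argmax, breaking exact ties toward the shorter period and
flagging maxima on the band boundary. No analytic significance test is
attached to the periodogram: rhythmicity is decided by the cosinor R²
below, and the two statistics are kept consistent by construction.

**Resolution and bias.** At a 4-day free-run span the grid step near 24 h is
about 0.2 h, which sets the quantization floor. On pure sinusoids recovery
is within one grid step anywhere in the band. On realistic signals —
oscillation riding on a decaying envelope, detrended with a moving average —
edge residuals leak a little power and can displace the peak by up to about
one further grid step, in a phase-dependent way (we verified the same
displacement appears in an independent Lomb–Scargle implementation given the
same preprocessed series). Group means are much less affected; the
end-to-end recovery error of group mean periods in the simulated study is
well under 0.2 h.

## Rhythmicity: cosinor fit and classification

The cosinor model \(y(t) = M + A\cos(2\pi (t-\phi)/\tau)\) is fit with
\(\tau\) fixed, which makes the model linear through
\(y = M + \beta_c \cos\omega t + \beta_s \sin\omega t\): ordinary least
squares gives the *exact* optimum that an iterative nonlinear fit would
approach, with no initialization or convergence concerns, and
\(A = \sqrt{\beta_c^2+\beta_s^2}\),
\(\phi = (\tau/2\pi)\,\mathrm{atan2}(\beta_s, \beta_c) \bmod \tau\).
\(R^2 = 1 - SS_{res}/SS_{tot}\) against the mean model (not adjusted R²;
with two effective regressors and ~150–300 points the difference is under
0.01 and never moves a 0.5 threshold materially). A free-period variant
(`cosinor_fit_free()`) profiles the fixed-period fit over a 0.05 h grid and
refines the optimum by golden-section search to 10⁻³ h — deterministic,
documented tolerances, no starting value.

Classification follows the standard two-epoch rule set:

* **Synchronized** (entrained epoch): fixed 24-h cosinor with R² ≥ 0.5.
* **Circadian** (free-run epoch): cosinor fixed at the Lomb–Scargle peak
  period, called Circadian when the period lies in the closed band
  [18, 35] h *and* R² ≥ 0.5. The reported period is the Lomb–Scargle
  estimate, so the period, amplitude, acrophase, and R² of a Circadian well
  all describe one and the same fit.
* Everything else is **Arrhythmic**. Thresholds are inclusive.

Both the degenerate-design guard (fewer than three distinct phases modulo
the period) and the behaviour of R² on pure noise (expected ≈ 2/(n−1),
stringently below 0.5 at n ≈ 200) are covered by tests; calibration runs of
200 noise wells and 200 high-amplitude wells bound the false-positive rate
at ≤ 10% and the detection rate at ≥ 90%.

## Phases and circular statistics

The **peak phase** of a well is the time of the global maximum of the
preprocessed trace within a one-cycle window, expressed in hours within the
cycle: for the entrained epoch the window is the last full cyclic day and
the anchor is ZT0 (the phase *is* the peak's ZT); for the free run it is the
first 26 h after release, anchored at the release time — the 2 extra hours
catch late first peaks of long-period genotypes. Ties break to the earliest
sample; a maximum at the window edge is flagged. The raw-maximum detector is
the most literal reading of "phase of the bioluminescent peak"; the cosinor
acrophase is available as an alternative detector via `cosinor_fit()`.

Phase sets are summarized on the circle: with
\(\theta_i = 2\pi\,\text{phase}_i/\text{cycle}\),
\(C = \overline{\cos\theta}\), \(S = \overline{\sin\theta}\), the mean
resultant length is \(R = \sqrt{C^2+S^2}\) and the mean phase is
\(\mathrm{atan2}(S, C)\) mapped back to hours (undefined, and reported
missing, when \(R\) is numerically zero, as for antipodal pairs). Uniformity
is tested with the Rayleigh statistic \(Z = nR^2\) using Zar's closed-form
approximation

\[ p = \exp\!\left(\sqrt{1 + 4n + 4(n^2 - (nR)^2)} - (1 + 2n)\right), \]

the standard choice in chronobiology toolkits. Monte-Carlo checks in the
test suite show the approximation is accurate to a few thousandths over the
relevant range (e.g. at n = 100, R = 0.05, and for the size of the test at
α = 0.05), with one known failure mode: exactly at R = 1 with tiny n the
true null tail is 0 while the approximation returns a small positive value
(0.034 at n = 3) — a regime never reached by real phase sets. The critical
circle for Rayleigh plots is obtained by bisecting the approximation
(`rayleigh_critical_R()`; for large n it approaches \(\sqrt{-\ln\alpha/n}\)).

Group phase summaries — like period summaries — cover rhythmic wells only:
a "peak time" read off an arrhythmic trace is noise, and published Rayleigh
plots for these assays are drawn for rhythmic populations.

## The synthetic-plate generator

Every analysis stage is validated against simulated plates with known truth.
A well's expected signal is

\[
L(t) = \text{bg} + B(t)\,[1 + a(t)\cos\psi(t)] + \text{mask}(t), \qquad
B(t) = B_0\,(1 - e^{-t/\tau_{acc}})\,e^{-t/\tau_{dec}},
\]

a *multiplicative* oscillation on a rising-then-decaying baseline envelope
(luciferase accumulation, \(\tau_{acc}\) = 8 h; substrate/ageing decline,
\(\tau_{dec}\) = 120 h) — the shape of real luciferase records, and the
reason detrending is non-trivially exercised. During cyclic epochs \(\psi\)
is phase-locked to the zeitgeber with the well's entrained acrophase
(default ZT 15 ± 1 h uniform jitter); from the moment of release it advances
at the well's endogenous period \(\tau_i\), drawn per well from a normal
distribution truncated to [18, 35] h. Rhythmicity is Bernoulli per well
(amplitude 0 when arrhythmic); in free run the relative amplitude (default
0.3) damps at 0.15/day, mimicking population desynchronization. Masking — a
direct, clock-independent response to the stimulus — is modeled separately
as a 10% additive transient in the first hour after each lights transition.
Counting noise is Gaussian with SD \(\sqrt{\max(\mu,1)}\) (Poisson-like), a
constant-SD Gaussian, or off. Blank wells carry background plus noise only.

Defaults are chosen to emulate the study conditions the package targets:
3 d entrainment + 4 d free run at 30-min sampling, ~5000-count baselines,
two groups of 30 wells with period means 24.4 h (control-like) and 26.4 h
(long-period-mutant-like), per-well period SD 1.0 h (real studies print only
group SEMs of 0.5–1.4 h at n of 9–39, which is consistent with a well-level
SD of about 1 h at those n), and 60% rhythmic wells (printed rhythmic
fractions run 38–64%).

Determinism: each well draws from a substream seeded from
(seed, well index), so a fixed seed is bit-reproducible and adding wells to
a configuration never changes existing wells.

**What the generator does not emulate** — and therefore what passing tests
do not demonstrate about real data: gradual re-entrainment dynamics after a
zeitgeber shift (phase-locking is instantaneous), well-to-well baseline
heterogeneity, developmental or positional trends across the plate,
non-sinusoidal waveforms, and the wide free-run phase dispersion seen in
real populations (simulated first-peak times are tight because they follow
deterministically from \(\tau_i\) and the entrained phase, so simulated
free-run resultant lengths run higher than published ones).

## Numerical choices and degenerate inputs

* Windowed means: inclusive window edges; integral (trapezoidal) mean for
  detrending, point mean for smoothing; both shrink at series edges; missing
  points contribute nothing and stay missing.
* Lomb–Scargle: requires ≥ 4 points, positive variance, span exceeding the
  shortest search period; the band is divided into a whole number of uniform
  frequency steps so both edges are on-grid.
* `best_period()` ties break toward the shorter period (deterministic);
  boundary maxima are reported with a message.
* Cosinor: requires ≥ 4 points spanning ≥ 1 period and ≥ 3 distinct phases
  modulo the period; solved by QR, not normal equations.
* Free-period search: 0.05 h profile grid, golden-section refinement to
  1e-3 h, deterministic.
* Circular mean: R below 1e-9 reports a missing mean phase rather than an
  arbitrary angle; Rayleigh p is clipped to (0, 1].
* Dead wells (all-zero or numerically zero initial maximum) error at
  normalization; the pipeline converts per-well errors into a `status`
  column rather than dropping wells.
* Analysis problem sizes used in the packaged validation: 60-well plates,
  192-point free-run segments, 20-replicate recovery studies, 10⁴-sample
  test-size calibrations, 10⁶-draw Monte-Carlo nulls.

## Known limitations

* Moving-average detrending biases period estimates by up to ~0.2–0.3 h on
  strongly decaying envelopes (edge effects); spline or LOESS detrending
  variants are out of scope in this version.
* The Rayleigh approximation's R → 1 small-n regime is inaccurate (see
  above); an exact-distribution option is not provided.
* No multi-component cosinor, damped-cosine fitting, imputation, actogram
  double plots, or multi-plate meta-analysis; group inferential statistics
  (ANOVA and post-hoc comparisons) are deliberately left to general-purpose
  statistics tools — the group summary CSVs are structured for direct
  consumption by them.
* Proprietary luminometer export formats are not parsed; users convert to
  the documented CSV layouts.
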