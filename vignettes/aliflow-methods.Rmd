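---
title: "Models and methods behind aliflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aliflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aliflow` is the computational layer of an air-liquid-interface (ALI)
microfluidic platform for organotypic brain cultures recorded on
multi-electrode arrays (MEA). It has four scientific parts — the liquid-level
control loop, the synthetic signal generators, the local field potential
(LFP) analysis and classification pipeline, and the rank-based proteomics
comparison — and this vignette explains the model, assumptions and numerical
choices behind each. Every empirical statement below is computed by the
package's own test suite or by `scripts/acceptance.R`; nothing is quoted from
external data.

## 1. The liquid-level control loop

An ALI culture sits on a shallow medium layer that evaporates quickly at
37 °C, so the platform measures the medium height with a laser distance
sensor (0.1 mm quantum) and regulates pump flow to hold a setpoint. The
controller is a positional-form discrete PID with rectangular integration
and a backward-difference derivative,

$$u(t) = K_p\,e(t) \;+\; K_i \sum_{\tau \le t} e(\tau)\,T_s \;+\;
K_d\,\frac{e(t)-e(t-1)}{T_s},$$

where $e(t)$ is setpoint minus measured level (mm), $T_s$ the control
interval and $u$ a dimensionless flow command converted to µL/min by the
pump gain. The one-step delay corresponds to the unit-delay operator of the
z-domain controller formulation. Among the discretizations consistent with a
"standard discrete PID" description, we chose the textbook
rectangular/backward-difference form; at the default proportional-only
gains the choice is immaterial.

The simulated plant is a mass balance for the open dish:
$\dot h = (q - q_\mathrm{evap})/(60\,A)$ with $h$ in mm, flows in µL/min and
dish area $A$ in mm². Around it the closed loop applies, per interval:
sensor quantization, the PID step, actuator saturation at `max_flow`
(with conditional-integration anti-windup: the integral accumulator is
frozen while the actuator is saturated — inactive at the default
$K_i = 0$ but required for full PID operation), and the plant update. A
disturbance is modelled as an instantaneous level step, agnostic to its
physical cause.

**The reference plant.** `reference_plant()` encodes the bench
configuration used for controller validation: a 6 mm diameter medium well
($A = 28.27$ mm²), a peristaltic pump delivering 5 mL/min per unit command
and saturating at 5 mL/min, 20 µL/min evaporation, 0.1 mm sensor quantum,
$T_s = 0.1$ s. These values were chosen jointly so that the loop's physics
make the controller's performance specification a genuine test: with
$K_p = 0.3$ the closed-loop time constant is
$\tau = 60A/(K_p G) \approx 1.13$ s, so a +2 mm step settles to within
0.2 mm of the setpoint inside 3 s without saturating the pump
(initial flow demand 3 mL/min). A much larger dish, or a weaker pump,
makes that convergence physically impossible — the maximum slew is
`max_flow`$/(60A)$ — which is why the well, not the whole culture dish
footprint, is the controlled surface. $T_s = 0.1$ s is fast relative to
the 3 s convergence window; the results are insensitive to halving it.

Numerical checks: a proportional-only loop with quantization, saturation
and evaporation disabled must match the analytic first-order decay
$e^{-t/\tau}$ within 1% per step (the per-step discretization bias is
$1 - (1-kT_s)e^{kT_s} \approx (kT_s)^2/2 \approx 0.4\%$ here); volume is
conserved to within one control step of flow; zero gains leave the level
governed by evaporation alone.

## 2. Synthetic MEA recordings

No raw recordings ship with the package; a seeded generator produces
condition-labelled sessions so that every downstream stage is testable.
Each electrode carries background noise synthesized in the frequency
domain with power shape $S(f) = 1 + 1/\max(f, 0.2)^{\alpha}$ (a $1/f$
long-range component over a white floor, $\alpha = 1$ by default), scaled
analytically so the unshaped background has exactly the requested SD.
Condition signatures are imposed as multiplicative amplitude gains on
frequency bands (power scales as gain²) and as Poisson-placed biphasic
spike templates (1.5 ms, sharp negative peak then a 0.35× positive
rebound — generic extracellular action-potential morphology) on a subset
of "active" electrodes. Each 10-s fragment is synthesized independently,
matching the fragment-wise unit of all downstream analysis; mixtures for
composite conditions are drawn at fragment granularity.

The built-in condition presets model the *directions* reported for
brain-derived extracellular vesicle (BDEV) experiments — vesicle addition
dampens firing and high-frequency oscillations (HFO, 80–600 Hz), the
exosome-secretion inhibitor GW4869 does not — with magnitudes that are
package defaults, fixed once and exposed in configuration:

| preset | firing rate | spike peak | band gains |
|---|---|---|---|
| CTL | 2 Hz | 8 SD | none |
| GW | 2 Hz | 8 SD | beta (13–30 Hz) × 1.3 |
| EV | 1 Hz | 8 SD | HFO (80–600 Hz) × 0.6 |
| GW_EV | — | — | fragment mixture (0.32, 0.57, 0.11) over (CTL, GW, EV) |

The 2 Hz / 8 SD baseline gives sparse but clearly detectable spontaneous
activity; the GW beta gain and the EV HFO attenuation are the minimal
distinguishable signatures that make the three-class problem learnable
without being degenerate. What the generator does **not** emulate matters
for interpreting green tests: no inter-donor or inter-slice variability, no
electrode drift or stimulation artifacts, no non-stationarity within a
session, and condition effects that are homogeneous across electrodes.
Classification performance on this synthetic family therefore demonstrates
that the pipeline's mechanics (feature construction, split, training,
repartition, statistics) are correct — not that real recordings of these
conditions are equally separable.

Synthetic protein tables follow the same philosophy: log-normal abundances
(log₂ baseline $\mathcal{N}(20, 2)$, within-sample spread 0.7), per-sample
multiplicative loading factors, an enriched subset shifted by a fold-change
in one condition, and intensity-dependent missingness (each sample's
abundances below its `missing_rate` detection quantile are censored) —
the data shape the rank-based statistics are designed to survive.

## 3. LFP analysis

**Spike detection** marks excursions of $|v|$ beyond 5.5 SD, with the SD
estimated per electrode on the full trace: full-trace estimation is stabler
than per-window SD and makes the Gaussian false-positive rate analytically
checkable ($2\bar\Phi(5.5) \approx 3.8\times10^{-8}$ per sample, about 0.05
expected events per electrode per 2 min at 10 kHz — the test suite verifies
the observed count over 100 seeded traces against the Poisson 99% interval).
The 10-ms rolling window acts as the merge/refractory scope: crossings
within one window of an accepted event are merged into it, and the event
time is the first crossing. Detection on the absolute value covers both
polarities; both the window and the sidedness are arguments. The detector
is invariant to sign flips and global rescaling by construction.

**Spectral analysis** splits each trace into consecutive non-overlapping
10-s fragments, removes each fragment's mean, and computes a one-sided
rectangular-window periodogram normalized as a density
($2|X_k|^2/(f_s N)$), so that $\sum \mathrm{PSD}\cdot\Delta f$ equals the
fragment variance (Parseval, tested to 1%). A 10-s fragment has native
resolution exactly 0.1 Hz, so the 0.2–300 Hz by 0.1 Hz analysis grid
(2999 bins) maps one-to-one onto periodogram bins with no interpolation.
Incomplete tail fragments are discarded. Band summaries average the
density over half-open bands $[lo, hi)$; because the HFO band extends to
600 Hz, past the 300 Hz spectrogram cap, `band_power()` computes a second
spectral pass from the raw recording when needed.

**Electrode selection** ranks electrodes by full-trace SD (averaged across
recordings when several are given) and keeps the top 20, ties broken by
lower id — a deterministic stand-in for "most active".

## 4. Classification

Features are fragment-level: per selected electrode, the 0.1-Hz power
densities are mean-pooled into 1-Hz bins (300 bins × 20 electrodes = 6000
features; raw 0.1-Hz resolution is available via `bin_hz = 0.1`), in
deterministic electrode-major order. The classifier is a random forest
(500 trees, $\sqrt{p}$ features per split, unlimited depth, seeded) trained
on a stratified fragment-level 70/30 split, with a stratified five-fold
cross-validation on the training portion reported alongside the held-out
accuracy as an overfitting check. Fragment-level splitting follows the
platform's analysis protocol literally; because fragments of one recording
are correlated, `group_by_recording = TRUE` offers the stricter
recording-level split, and on the default synthetic family (independent
fragments) the two coincide in distribution.

Two report quantities mirror the platform's figures. *Class repartition*:
for a tested condition, the fraction of its fragments assigned to each
trained class. *Confidence upon prediction* (CUP): the mean predicted
probability of the winning class over test fragments — the natural reading
of the term, flagged here as an interpretation. Repartitions are compared
to the uniform random-assignment null ($100/k\%$ per class, 33.3% for
three classes) by a chi-square goodness-of-fit test on assignment *counts*
($k-1$ degrees of freedom); a composite condition is never part of the
training classes by default. For mixtures of trained classes, the
repartition is a consistent estimator of the mixing weights; the test
suite checks recovery at 500+ fragments against the generating
(0.32, 0.57, 0.11) weights.

**Problem sizes.** The packaged three-class experiment uses 50 one-minute
recordings per class at 2.5 kHz with 24 electrodes (top 20 selected),
i.e. 300 fragments per class, plus 504 composite-mixture fragments. These
sizes are the package's choice of a desk-scale experiment: 2.5 kHz keeps
the full 0.2–300 Hz feature grid and the 600 Hz HFO edge below Nyquist
while keeping the run in minutes, and accuracy/CUP are already saturated
at this size. The 60-electrode, 10 kHz, 2-minute session defaults of
`recording_spec()` reflect the acquisition geometry the generator
emulates.

## 5. Rank-based proteomics

The comparison pipeline is built for condition designs whose per-sample
loading cannot be assumed equal, in five stages:

1. **Presence filter** — keep a protein only if some condition detects it
   in strictly more than 75% of its samples (so 3 of 4 is *not* enough).
   Raising the threshold can only shrink the set (tested monotonicity).
2. **Imputation** — undetected values become the sample's 2.5%
   linear-interpolation quantile of detected abundances, per sample
   (left-censoring model). The detection mask is preserved rather than
   overwritten: filtering and ranking keep seeing true detection status,
   so filter∘impute and impute∘filter agree on the survivor roster and on
   every detected value (the imputed constant itself depends on which
   proteins are present when the quantile is taken, so it may differ
   slightly between the two orders).
3. **TMM scale factors** — the trimmed-mean-of-M-values algorithm
   (upper-quartile reference selection, library-size-normalized M and A,
   30%/5% double trimming, delta-method precision weights), implemented
   in-package and cross-checked in the tests against the edgeR
   implementation on the same matrix. `tmm_factors()` returns *effective*
   scale factors (library size × TMM factor, geometric mean 1): a sample
   loaded at 4× its twin gets a factor exactly 4× larger. Because the
   precision weights depend on absolute abundances, equivariance under
   rescaling a single sample among many is near-exact rather than
   bit-exact.
4. **Ranks** — within each sample, rank 1 is the most abundant protein,
   ties get average ranks, and undetected proteins share the worst tied
   rank so rank averages remain comparable across samples of different
   detection depth. The entire rank pipeline is invariant to any
   per-sample monotone transform of abundances — the reason to use ranks
   when loading is not normalizable.
5. **Differential comparison** — per protein, a two-sided rank-sum test
   between the two conditions' rank vectors with Benjamini–Hochberg
   adjustment. This is a deliberate substitution for a count-model GLM:
   the intent (normalized differential comparison) is preserved while
   staying within rank statistics; type-I calibration at the nominal 5%
   level is part of the test suite. With $n$ samples per condition the
   smallest attainable two-sided p-value is $2/\binom{2n}{n}$, so designs
   below $n = 4$ cannot reach conventional significance after adjustment.

Top-N lists (smallest condition mean rank, ties by id) and overlap
percentages connect to ontology tooling: lists are exported in RNK form
rather than enriched in-package. Overlap is shared-over-union, reported as
a whole percentage *truncated* (floor) to match printed precision — for
lists sharing 95 of a 117-protein union this gives 81%; truncation, unlike
half-up rounding, is consistent with all the overlap figures this
percentage convention is meant to reproduce.

## 6. Reproducibility mechanics

All randomness flows from one top-level seed through named sub-streams
(`derive_seed(seed, stage)`, a polynomial hash kept below $2^{31}$), so
any stage can be re-run in isolation and a full `run_pipeline()` is
bit-reproducible. Generators are bit-reproducible under a fixed seed.
Configuration is YAML with unknown keys rejected, and each pipeline run
writes its resolved configuration next to its outputs.

Degenerate inputs are handled explicitly: zero-variance traces detect zero
spikes with a warning; a dry dish clips at level 0 with a warning; a
diverging control loop aborts with a diagnostic rather than returning a
runaway trace; all-missing samples refuse imputation; chi-square tests
warn when expected counts fall below 1.

## 7. Known limitations

- The synthetic signal family is stationary and electrode-homogeneous;
  results on it bound pipeline correctness, not real-data separability.
- Effective condition effect sizes (firing ×0.5, HFO ×0.6, beta ×1.3) are
  defaults of the generator, not measured quantities.
- The rank-sum differential test discards abundance magnitudes; with few
  samples per condition its resolution is limited by the discreteness of
  the exact null.
- The plant model is a single lumped volume; it ignores pump pulsation,
  sensor noise beyond quantization, and spatial level gradients.
- Fragment-level splitting can flatter accuracy when fragments within a
  recording are correlated; use `group_by_recording = TRUE` for the
  conservative protocol.
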