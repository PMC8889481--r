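---
title: "Methods: pulse-oximeter validation analytics in oxival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse-oximeter validation analytics in oxival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxival)
```

## Scope and model

`oxival` analyses controlled validation sessions in which participants wear
one or more pulse oximeters while arterial blood gas (ABG) samples provide
gold-standard SaO₂ readings. A session has two phases: a *movement phase*
at near-normal saturation, in which seven activity strata (rest,
sit-to-stand, tapping, rubbing, drinking, page turning, tablet use) stress
the optical signal, and a *hypoxia phase* in which inspired oxygen is
lowered so SaO₂ descends through stable plateaus at 95, 90, 87, 85, 83 and
80%. Every ABG yields one reference sample; every reference is paired with
one windowed summary of each device's 1 Hz SpO₂ stream. All statistics
operate on these matched pairs.

## Pairing rules

The unit of analysis is the *windowed median*: robust to isolated artifact
spikes and to one-sided clipping at 100%, and insensitive to sample order.

* Movement phase: median SpO₂ over `[stop − 40 s, stop)` for each task,
  paired with the ABG drawn at the task's end. The window is half-open so
  the sample at the stop instant — already outside the task — is excluded.
* Hypoxia phase: median over `[t − 35 s, t + 5 s]` around the ABG time
  `t`, both endpoints included (41 samples at 1 Hz). The 5 s tail
  reflects circulatory plus device-averaging delay between arterial blood
  and the finger reading.
* A pair is emitted only if the window holds at least `min_valid_samples`
  non-missing samples (default 20, half the nominal window). Published
  validation tables show per-task "available points" below the session
  count without stating the rule; this threshold is our explicit,
  configurable proxy. Emitted + dropped counts always sum to the reference
  count, per device, and both are reported.
* Windows truncated by the stream boundary are used (with a warning) if
  they still meet the threshold, preserving data at phase edges.
* Mid-task sit-to-stand references are routed exclusively to the paired
  mid-vs-end Wilcoxon comparison; they never enter accuracy metrics, whose
  windows correspond to end-of-task ABGs only.
* Hypoxia pairs carry an SaO₂ subgroup: severe (< 85), mild (85–89.99),
  normoxia (≥ 90). Boundary values go up: 85.0 is mild, 90.0 is normoxia.

## Accuracy metrics

For pairs \((S_i, R_i)\) (device median, reference SaO₂), with
\(d_i = S_i - R_i\):

* RMSE (the ISO A\(_{rms}\)): \(\sqrt{\tfrac1n\sum d_i^2}\). The identity
  \(\mathrm{RMSE}^2 = B^2 + \tfrac{n-1}{n}\,\mathrm{var}(d)\) is asserted
  property-style in the test suite.
* Mean bias \(B = \bar d\) and mean absolute bias \(\overline{|d|}\).
* Precision \(S\): the SD of residuals of the ordinary least-squares fit
  of \(S_i\) on \(R_i\). Denominator \(n-2\) (the regression's residual
  degrees of freedom); the source convention is unstated, so an \(n-1\)
  option is exposed (`ddof = 1`). Constant-SaO₂ strata raise a
  degenerate-regression error naming the stratum rather than returning 0.
* Bland–Altman: \(B \pm 1.96\,\mathrm{SD}(d)\), SD with \(n-1\).
* ISO verdict: pass iff RMSE ≤ 4 *and* bootstrap CI upper bound ≤ 8, both
  inclusive; the sample check requires ≥ 200 pairs from ≥ 10 subjects with
  no 5-point SaO₂ bin in [70, 100] holding more than 40% of points. The
  bin rule is a documented proxy — the standard's exact plateau-balance
  table is not public in the source we follow.

### Bootstrap

Confidence intervals are percentile intervals over resampled *pairs*
(default 10,000 repetitions), matching the plain description of the
original analysis; BCa was deliberately not used. The resampling unit is
the pair, treating within-participant pairs as independent — faithful to
the source analysis, not an endorsement; a cluster bootstrap by session
(`cluster = "session_id"`) is exposed for sensitivity analysis. Detection
metrics resample within each true class separately, preserving prevalence
(the source is silent; unstratified resampling could produce single-class
resamples in which sensitivity is undefined). All bootstraps are
deterministic given a seed.

## Between-stratum tests

The table-footnote battery: one-way ANOVA followed by Tukey–Kramer on mean
(or absolute) bias, Levene on precision, all two-sided at α = 0.05.

* ANOVA is computed from sums of squares; Tukey–Kramer uses studentized
  range probabilities with the unequal-\(n\) standard error
  \(\sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}\).
* Levene is the classic mean-centered form, as cited in the source;
  Brown–Forsythe (median-centered) is an option.
* The paired Wilcoxon signed-rank test drops zero differences (Wilcoxon
  convention; Pratt handling is an option) and uses the exact null
  distribution for n ≤ 25, computed by convolution over midranks (so tied
  absolute differences are handled exactly); above that, a normal
  approximation with tie and continuity corrections. Exactness is verified
  against full sign-pattern enumeration in the tests.

## Hypoxemia detection

Condition positive is SaO₂ < 90; SaO₂ = 90.0 is normoxic, mirroring the
subgroup rule. Predicted positive is *strictly* SpO₂ < cut-off: published
optimal cut-offs (e.g. 90.7, 88.0) fall between achievable thresholds,
implying a sweep over observed scores, and the strict rule makes the
boundary case (SpO₂ exactly 90 at cut-off 90 → predicted negative)
well-defined and tested. Baseline 100%-target windows are condition
negative and are included. The ROC sweep visits every distinct observed
median plus a sentinel above the maximum; AUROC is the trapezoidal area,
equal to Mann–Whitney concordance with ties counting ½ (property-tested
against brute-force concordance). The "optimal operating value" is the
Youden-J maximizer — the source says only "best compromise between
sensitivity and specificity" — with ties broken toward the *higher*
cut-off, i.e. toward sensitivity, the clinically conservative side.
Degenerate sweeps where J never exceeds 0 return the sweep end with a
warning. Undefined rates (zero denominators) are reported as `NA` with a
warning, never as 0.

## The simulator

The generator exists so that every stage of the pipeline can be tested
against known ground truth; its defaults encode the study protocol it
emulates.

* Protocol: seven tasks (rest 120 s; 20 sit-to-stands ≈ 90 s; 2-minute
  tapping and rubbing; 20 sips ≈ 100 s; 50 pages ≈ 150 s; tablet ≈ 300 s)
  with 30 s rests between; then six descending hypoxia plateaus (90 s
  each, 30 s logistic transitions) after a 300 s repositioning gap. Task
  counts and the timed task durations come from the protocol; gap lengths,
  plateau and transition durations are realistic session-logistics
  choices, made once.
* Trajectory: participant baseline ~ N(99.3, 0.4) truncated at 100
  (matching a cohort whose median baseline SaO₂ is ≈ 99.6); a
  raised-cosine transient dip during sit-to-stand with depth
  ~ N(1.87, 0.87) truncated at 0, full at the task midpoint and recovered
  by the stop (so mid-task ABGs read lower than end-of-task ones by that
  amount, the basis of the Wilcoxon comparison); plateaus are exactly
  flat at their targets with normalized logistic transitions; white
  physiological jitter of SD 0.3% is added everywhere and the curve is
  clipped to [70, 100]. The within-plateau 0.3% SD is a modelling choice —
  no variability figure is published — as is the transition shape, which
  is non-critical because metric windows sit inside plateaus.
* Device model: trailing moving-average smoothing (vendor data averaging),
  additive systematic bias (optionally linear in SaO₂), white Gaussian
  scatter, task-window artifact noise with typically negative mean
  (motion makes oximeters under-read), and task-specific dropout. Values
  are clipped to [0, 100] before dropout thinning.
* References: one ABG at each task stop (+ optional mid-STS), one at each
  plateau midpoint (the near-100% baseline plateau included, giving 7
  movement + 7 hypoxia references per session); reference SaO₂ = trajectory
  value + analyzer noise (SD 0.2%, a calibrated-analyzer figure chosen in
  the absence of a published one).
* Determinism: one master seed expands into per-session and per-stage
  child seeds via `split_seed()` (a fixed-size draw under the master seed,
  so child streams do not depend on how much randomness each stage
  consumes). Identical configuration and seed give identical datasets,
  byte-identical after serialization.

### What the simulator does *not* emulate

Device error is white in time, so the 40-sample windowed median shrinks it
by roughly \(\sqrt{\pi/2}/\sqrt{41}\); real oximeter error is strongly
autocorrelated (perfusion, posture, calibration), so real pair-level
scatter is much larger than the simulator's at the same 1 Hz scatter. A
green parameter-recovery test therefore establishes that the pipeline
measures what the generator injects — not that any physical device meets
ISO limits. Waveform-level artifacts, FiO₂/hypoxicator physics, heavier
tailed artifact distributions and inter-device clock drift (devices share
one clock, as in the synchronized source protocol) are all out of scope.

### Closed-form check used in acceptance testing

For a no-motion device with bias \(b\) and 1 Hz scatter \(\sigma\), the
hypoxia-phase pair difference is approximately
\(d \approx b + \mathrm{med}_{41}(\varepsilon) - \nu_{ref} - \eta\), giving
\[
\mathrm{RMSE}^2 \approx b^2 + \underbrace{\tfrac{\pi}{2}\sigma^2/41}_{\text{median attenuation}}
 + \sigma_{plateau}^2 + \sigma_{abg}^2 .
\]
The acceptance suite verifies the pipeline against this closed form within
5% and recovers \(b\) within 3 standard errors, pooled over 20 replicate
33-session studies under a seed fixed before the expected outcomes were
computed.

## File format and numerical conventions

Sessions are directories of comma-separated text files (see the README
table) with full-precision (`%.17g`) numeric serialization, so
write-then-read is bit-exact — including dropout gaps, which round-trip as
blank fields. Times are seconds from session start; wall-clock conversion
is outside the metric path. Unknown task labels are rejected at parse time
rather than passed through, keeping every downstream stratum well-typed.
Reported tables retain full precision in machine-readable output; rounding
to 2 decimals is left to presentation.

## Known limitations

* Pairs from one participant are treated as independent by the ANOVA
  battery and the default bootstrap, reproducing the source analysis; the
  cluster bootstrap option quantifies (but does not remove) the resulting
  optimism.
* The ISO balance rule is a proxy (≤ 40% of points per 5-point bin).
* The percentile bootstrap undercovers slightly for variance-like
  statistics at moderate n; empirical coverage for the RMSE CI at n = 215
  is ≈ 94% in the acceptance experiment.
* Detection-table class counts are reported per device so that windows
  lost to dropout are visible rather than silently renormalized.
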