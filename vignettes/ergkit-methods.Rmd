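---
title: "Simulating and scoring electroretinograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring electroretinograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergkit)
```

## The problem

Full-field electroretinography (ERG) records the retina's massed electrical
response to calibrated light flashes. Three readouts carry most of the
information in rodent studies of retinal disease:

* the **a-wave**, the initial negative deflection driven chiefly by
  photoreceptors — here defined as the most negative point of the averaged
  trace;
* the **b-wave**, the following positive deflection driven by inner-retinal
  (bipolar/Müller) activity — the most positive point, with no removal of
  oscillatory potentials before peak picking;
* the **oscillatory potentials (OPs)**, high-frequency (~100–120 Hz in
  mouse) wavelets riding on the b-wave rising phase, generated by
  inner-retinal circuitry. They are isolated with a 25 Hz high-pass filter
  and scored as the root-mean-square of the filtered trace, normalized by
  the same trace's b-wave amplitude.

In models of early diabetic retinopathy, OP changes can appear while a/b
amplitudes are still normal, so a pipeline must be able to detect a
scotopic-OP-specific deficit against unchanged a/b endpoints. `ergkit`
provides the whole chain — synthetic cohort generation, feature extraction,
OP scoring, and the split-plot statistical layer — so that the chain's
operating characteristics (type-I error, power) can be measured by Monte
Carlo.

## The generative waveform model

No standard closed-form equation exists for an ERG trace, so the simulator
uses an additive model chosen for analytic tractability: extraction can be
validated against exact ground truth. On a millisecond axis anchored at
flash onset,

$$
V(t) = -\tilde A_a\, g(t; t_a, w_a) + \tilde A_b\, g(t; t_b, w_b)
     + A_{op}\, g(t; t_{op}, w_{op}) \sin\!\big(2\pi f_{op}(t - t_{op})/1000\big)
     + \varepsilon(t),
$$

with Gaussian bumps $g(t; c, w) = \exp(-(t-c)^2 / 2w^2)$, white noise
$\varepsilon \sim N(0, \sigma^2)$, and the deterministic part set to zero
before onset. The a- and b-amplitudes grow with flash strength via the
Naka–Rushton relation $R(I) = R_{max} I^h / (I^h + I_{50}^h)$ (intensities
are stored in log~10~ cd·s/m², the ERG convention, and converted to linear
units first). The OP envelope amplitude is not intensity-scaled.

Defaults follow typical adult mouse physiology and are all overridable:
$t_a = 18$ ms, $w_a = 7$ ms, $A_a = 150$ µV; $t_b = 50$ ms, $w_b = 18$ ms,
$A_b = 300$ µV; $f_{op} = 110$ Hz, $t_{op} = 32$ ms, $w_{op} = 8$ ms,
$A_{op} = 30$ µV; $\sigma = 4$ µV; $I_{50} = 0.1$ cd·s/m², $h = 1$,
$R_{max} = 1$ (a dimensionless gain, so $A_a$, $A_b$ are the saturated
amplitudes). Traces are sampled at 2000 Hz over 180 ms with a 20 ms
pre-stimulus baseline. None of these constants is claimed from any
particular instrument; they are simulator configuration.

Two consequences of the model are worth knowing:

* **Onset discontinuity.** Zeroing the signal before the flash makes the
  waveform discontinuous at onset by $g(0)$ of each component. At the
  defaults this step is at most ~4% of $A_a$ and is irrelevant; with wide,
  early components (say $w_a \ge 15$ ms at $t_a = 18$ ms) the step carries
  broadband energy through any high-pass filter. Validation configurations
  that need spectrally clean slow components therefore place the bumps
  well inside the record.
* **Leakage into the OP band.** A 7 ms Gaussian a-wave has real energy
  above 25 Hz; the filtered trace is OPs *plus* a deterministic sliver of
  the fast a-wave edge. This mirrors what the same filter does to real
  recordings. It inflates the OP RMS additively (in quadrature) and equally
  across groups, diluting but never masking multiplicative OP effects.

## The synthetic cohort

`study_design()` crosses genotype labels with `STZ`/`vehicle`, each group
carrying `n` subjects observed over a scotopic (default 5 flashes, −3…1
log cd·s/m²) and a photopic (default 4 flashes, −1…0.5) series.
`effect_model()` applies strictly positive multiplicative factors to one
waveform component (`a`, `b`, `op`) in one adaptation state for one group —
a scotopic-OP-only deficit is a single row with factor < 1 — so the null
model (no rows) generates exchangeable groups by construction.

Each subject draws one lognormal amplitude scale (mean 1, CV 0.2 by
default) shared across all of that subject's traces. This is the crucial
realism ingredient: it induces the within-subject correlation that the
split-plot ANOVA's two error strata exist to model; without it the
between-subject stratum would be degenerate. Glycemia is baseline
$N(150, 15)$ mg/dL plus a treatment shift (default +300 for STZ) after the
induction week; weight gain is mildly blunted under STZ. These vitals are
plumbing for the cohort table, not physiological claims.

Each (subject, stimulus) yields one already-averaged trace by default,
since sweep counts in typical protocols vary; `average_traces()` is
available when per-sweep simulation is configured. One averaged trace per
mouse per stimulus is used throughout (the eye field is retained for
generality).

What the simulator does **not** emulate: drifting baselines, mains hum,
blink/movement artifacts, intensity-dependent implicit-time shifts,
photoreceptor adaptation between flashes, or mortality. Passing tests
therefore demonstrate that the pipeline recovers what this model encodes —
not that it is robust to every artifact of real recordings.

## Feature extraction

Extraction reproduces point-picking on the averaged trace: baseline = mean
of pre-stimulus samples; a-trough = global minimum in a configurable
post-onset window (default 0–50 ms); b-peak = global maximum after the
a-trough, OPs included. `a_amp` is baseline-to-trough; `b_amp` is
trough-to-peak, the dominant ERG convention (baseline-to-peak is available
via `feature_windows(b_amp_mode = "baseline_to_peak")` since point-picking
tools differ). Implicit times are reported on the sample grid without
interpolation, and ties at equal extreme values resolve to the earliest
sample, for determinism. A trough or peak landing on a window boundary is
flagged in the record's provenance rather than silently accepted.

## OP isolation and the normalized RMS

The filter is an order-4 Butterworth high-pass cornered at 25 Hz, applied
forward and backward (zero phase) over an odd-reflection-padded signal.
Zero-phase filtering preserves OP timing (a passband peak moves by less
than one sample); the realized gain is ≤ 10⁻²⁰ at DC and ≥ 0.99 from 100 Hz
up, verified against the transfer function. Only the 25 Hz corner is a
domain constant; family, order and phase handling are configuration
(`filter_spec()`).

The RMS window defaults to each trace's own a-trough-to-b-peak span — the
OPs ride the b-wave rising phase, and a landmark-anchored window follows
latency shifts between animals; a fixed window is available. The statistic
is `op_rms / b_amp`. Normalizing the waveform first and then taking the RMS
is algebraically identical for a per-trace scalar normalizer, so the
simpler order is used. The ratio is invariant under uniform voltage
rescaling of the recording (re-extracting features first), which is what
makes it comparable across animals of different overall response size —
the subject-level amplitude scale largely cancels, so group effects on OPs
are tested against a much smaller residual variance than raw amplitudes
would allow.

## The statistical layer

`mixed_anova()` implements the classic split-plot decomposition — between
stratum: group and subjects-within-groups; within stratum: intensity,
group × intensity, residual — with F tests against the correct stratum
error. Unbalanced group sizes (real cohorts run n ≈ 4–13/group) use the
weighted-means decomposition on group means weighted by n; with complete
within-subject data this is orthogonal, so main effects are not
contaminated by the interaction. The SS partition and df identities are
asserted on every fit. No sphericity correction is applied by default,
matching the longstanding behavior of the commercial software family such
analyses usually run in; a Greenhouse–Geisser adjustment (eigenvalue form
of epsilon on the pooled within-group covariance) sits behind
`gg_correction = TRUE`.

`bonferroni_posthoc()` compares groups at each intensity. A simple effect
at fixed intensity mixes between- and within-subject variance, so the
error term pools the two strata,
$MS_{pooled} = (SS_{subj} + SS_{resid}) / (df_{subj} + df_{resid})$, with
the pooled df — the standard approach for simple effects in mixed designs.
Adjustment is $\min(1, m\,p)$ with $m$ = pairs × intensities. Both
all-pairs and versus-reference modes are supported (figure asterisks are
often drawn against a control genotype); all-pairs is the default.
`ttest_unpaired()` is the classic pooled-variance two-sample test for
single-endpoint comparisons such as endpoint glycemia. Report formatting
uses the conventional asterisk ladder (*P < 0.05; **P < 0.01;
***P < 0.001; ^P < 0.0001).

## Monte Carlo operating characteristics

`operating_characteristics()` repeats simulate → extract → fit over
replicates and reports, per endpoint (scotopic/photopic × a, b, normalized
OP RMS), the fraction of replicates with a significant group main effect.
Under the null model this estimates type-I error; the suite checks it lands
near the nominal 5% (500 replicates, 2 × 8 subjects). Under a
scotopic-OP-only multiplier of 0.7 in one of four groups at n = 7, the
scotopic-OP endpoint shows high power while photopic-OP and all a/b
endpoints stay near nominal — the dissociation pattern the pipeline exists
to detect. Problem sizes (500 and 200 replicates, the 2×8 and 4×7 designs)
were fixed once as stable-yet-desk-scale choices; binomial standard errors
at those sizes are ≤ 0.016.

## Numerical and degenerate-input choices

* Flat traces, all-identical responses, subjects missing intensity levels,
  groups with a single subject, zero b-amplitude normalizers, cutoffs at or
  above Nyquist, and windows outside the record all raise immediate,
  specific errors; listwise removal of incomplete subjects is opt-in
  (`drop_incomplete = TRUE`).
* All simulation is a deterministic function of the design seed (the RNG
  state is restored afterwards), so identical configuration ⇒
  byte-identical output bundle; the run manifest records the configuration
  hash.
* Voltages serialize at 6 significant digits in TSV; reloading and saving
  again is byte-stable, and the time grid is reconstructed from `fs` and
  `t0_ms` rather than stored per sample.

## Known limitations

The generator's additivity means component overlap shifts extrema slightly
(extraction is validated against numerically computed extrema of the
continuous model, not against the raw input amplitudes); OP leakage from
the sharp a-wave is physical but means `op_rms` is never a pure OP
measure; the split-plot model assumes homogeneous between-subject variance
across groups and no sphericity violation by default; and no attempt is
made to model real instruments' amplifiers, notch filters, or export
formats beyond a simple TSV dialect.
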