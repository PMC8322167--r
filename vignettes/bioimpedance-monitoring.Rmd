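---
title: "Monitoring secondary brain injury with multichannel bioimpedance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring secondary brain injury with multichannel bioimpedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimon)
```

## The monitoring problem

Intracranial pressure (ICP) rises whenever volume is added inside the rigid
skull — by an expanding hematoma, an inflating lesion, or diffuse edema — but
the pressure alone cannot say *what* is happening. A focal ischemia-like mass
effect and an active bleed both raise ICP, yet demand opposite management.
Tissue bioimpedance breaks this degeneracy: blood conducts far better than
brain parenchyma (≈0.7 S/m vs ≈0.2 S/m), so a conductive (hemorrhagic)
lesion *lowers* the measured impedance while an insulative (ischemia-like)
mass *raises* it. Eight tetrapolar channels, formed by rotating a
scalp-electrode pair around fixed intracranial electrodes, add coarse
spatial information in the form of eight angular sensitivity sectors.

`bimon` implements the full analysis chain for such a monitor, together with
a ground-truthed simulator of the in vivo validation experiment: a staged
protocol of balloon inflation (high-impedance focal injury), deflation,
autologous-blood injection (low-impedance focal injury), an osmotic-therapy
phase and a terminal phase (both global). Everything downstream — artifact
filtering, de-trending, event metrics, detection, localization and the
focal/global statistics — operates identically on simulated or imported
recordings.

## The simulator: a stated world

The simulator is first-class code, not a test fixture. Its defaults *are*
the stated experimental world; they were chosen once, from the experiment's
description and from what a practitioner would call realistic, and they are
not tuned against test outcomes.

**Protocol** (`default_protocol()`): 30 min baseline; inflation in 12 steps
of 0.1 mL every 5 min to 1.2 mL; mirrored deflation over 1 h; blood
injection in 6 steps of 0.2 mL every 5 min to 1.2 mL; 30 min osmotic phase;
15 min terminal phase. A compliance-balloon check follows every mass-effect
step by 2 min and is recorded as a sync event, because the impedance
measurement windows must never overlap it.

**Signal chain**: the monitor multiplexes 8 channels, 10 s each (80 s
period), and reports impedance magnitude at 50 Hz (1000-sample averages of a
50 kHz carrier). Envelope-level synthesis reproduces exactly this output
contract: per-channel samples only within that channel's active slot, at a
configurable in-slot rate `fs` (default 50 Hz). Because every analysis
quantity is a 10 s slot mean, reducing `fs` only rescales slot-mean noise;
the Monte-Carlo test sweeps use `fs = 1` Hz for speed and say so.

**Forward model**: a focal injury of volume $V$ in sector $s$ changes channel
$c$ by
$$\Delta Z_c(t) = \sigma \, g \, V(t) \, w_c, \qquad
  w_c = \exp\!\left(-\tfrac{d(c,s)^2}{2\kappa^2}\right),$$
with contrast sign $\sigma$ (+1 balloon, −1 blood), focal gain $g$ (default
30 Ω/mL at the nearest channel, consistent with tens-of-ohms per-channel
responses at full inflation), wrapped angular distance $d$ and kernel width
$\kappa$ (default 45°, one sector). No quantitative forward model linking
inclusion volume to per-channel impedance exists in the source experiment;
the Gaussian-kernel linear-gain model is this package's own, and is the
simplest monotone-decay model consistent with eight angular sectors. Global
events add a uniform shift (default 15 Ω) on all channels, ramping over the
first half of their phase. An optional `tracking_fraction` diverts part of
the injected blood volume away from the focal sector, emulating posterior
blood tracking.

**ICP**: the classic single-exponential craniospinal pressure–volume
relation, $ICP(t) = p_0 e^{eV(t)}$, with $p_0$ drawn per subject in
8–15 mmHg (the wide baseline range seen across animals) and elastance
$e = 0.5\,\mathrm{mL}^{-1}$, reproducing monotone, stepped ICP during
inflation. The osmotic phase removes an effective volume (default 1 mL) as a
ramp; the terminal phase decays ICP toward zero with a 2 min constant.

**Noise and drift**: per-sample Gaussian noise defaults to
`noise_sd_for_snr(84, 1000)` ≈ 0.063 Ω, i.e. the system's 84 dB sample SNR
at a 1000 Ω baseline; baselines are drawn per channel in 1000 ± 10% Ω.
Electrode settling is a saturating exponential rise (20 Ω, τ = 300 s) plus a
linear trend (10 Ω/h). The settling constant matters: the de-trending step
assumes residual drift is linear over the final 10 min of baseline, so the
stated world settles essentially within the 30 min baseline. A much slower
settling would violate the method's own stated assumption, not test it.

**Artifacts**: three classes are simulated and filtered — CT-acquisition
noise bursts (all channels), persistent DC shifts on single electrodes, and
decaying droplet offsets (fluid on an electrode). The exact quality criteria
of the original filtering protocol are unpublished; the thresholds here
(window 60 s, step threshold 20 Ω, masked-fraction 0.5, one unrepaired step)
are original to this package, explicit, and configurable, and every
exclusion is reported with its reason.

**Carrier level**: `synthesize_carrier_block()` and the matched-filter
demodulator exercise the path from raw 50 kHz voltage/current waveforms to
the 50 Hz impedance stream. A 50 kHz carrier cannot be quadrature-demodulated
from 50 kHz samples (it aliases to DC), so carrier synthesis requires
`f_sample >= 4 * f_carrier` (default 250 kHz) and refuses anything less;
envelope-level synthesis is the default path.

## The analysis chain

**Demodulation.** Block-wise matched filtering:
$A = \tfrac{2}{N}\sqrt{(\sum x\cos\omega k)^2 + (\sum x\sin\omega k)^2}$,
$Z = A_V / A_I$ per 20 ms block. Partial trailing blocks are dropped rather
than zero-padded (padding biases amplitudes at slot edges); blocks whose
current amplitude falls below 1 µA — far under the 0.5–5 mA source range —
are flagged unusable instead of producing unbounded ratios.

**Preprocessing.** Filtering is a mask-only contract: sample values are
never altered, masked samples are excluded from window means rather than
interpolated (interpolation would manufacture data inside CT bursts).
Step-artifact detection compares medians of adjacent 60 s windows, robust to
the 80 s multiplexing gaps. A detected change within one window of a
protocol volume step is attributed to the protocol: the natural "within one
step interval" rule degenerates when steps recur every interval (every
instant would be synchronous), so the tolerance equals the detector window.
After a step, samples are masked until the windowed median returns to its
pre-step level; a persistent DC shift therefore masks to the end of the
trace while a droplet transient masks only its own span. De-trending fits a
line to the final 10 min of baseline per channel and subtracts its
extrapolation from there to the end of the recording, so the zero-volume
reference and all later event windows share one drift-corrected frame;
stopping the subtraction mid-recording would mix corrected and raw
references.

**Event metrics.** Per channel and event: the zero-volume impedance is the
mean over the 80 s (one full multiplexing cycle) before the event; each
volume step's impedance is the usable 10 s slot nearest the midpoint of its
static window, never overlapping a compliance check (equidistant slots
resolve to the earlier one — deterministic and causal); $\Delta Z$ is final
minus zero-volume impedance; $\Delta ICP$ the matching ICP change; the
discriminatory index is $DI = \Delta Z / \Delta ICP$, undefined below a
0.1 mmHg pressure response; impedance–ICP Pearson correlation pairs slot
means of both streams. Detection scans the per-step across-usable-channel
mean change (or a designated nearest channel) against a threshold of 7.1 Ω —
the system's SNR-derived resolution with a 10× safety factor. The threshold
is configuration, not recomputed: the reference level of its derivation is
not stated, so recomputing it would be an invention.

**Localization.** Each event's 8-channel $\Delta Z$ vector is min–max
rescaled to $n\Delta Z \in [0,1]$. Dividing by the maximum — the other
reading of "normalized to the maximum element" — cannot reach 0 for positive
vectors and breaks for sign-mixed ones, so min–max is used and flagged as an
interpretation. A vector whose across-channel range is below the detection
resolution (default 7.1 Ω) carries no spatial information: rescaling it
would manufacture a full 0–1 spread out of noise, so it is treated as
degenerate (all 0.5), extending the exact-equality degenerate rule to
equality within measurement resolution. Cohort maps average subject maps
elementwise; the threshold classifier labels an event focal-low-impedance if
any element falls below 1/3 (minimum element is the injury element),
focal-high-impedance above 2/3 (maximum element), and global when everything
stays inside (1/3, 2/3). Because min–max pins one element to 0 and one to 1
per subject, cohort means routinely cross *both* thresholds; the focal
element is then the extreme isolated from the bulk of the map — if the map's
median lies below 0.5 the high outlier is focal, and vice versa — falling
back to the larger deviation from 0.5 only for an exactly central median. A
tie-break on deviation alone is degenerate here (both deviations are exactly
0.5 whenever subjects agree on the extremes). Classification runs on cohort
means by default, with a per-subject mode for single-patient use.

**Focal vs global statistics.** A focal event drives one sector far harder
than the rest; a global event moves all channels together. The
across-channel variance of $\Delta Z$ per subject-event is compared between
classes by: a Levene test (mean-centred ANOVA on absolute deviations —
robust to non-normality at these sample sizes; Brown–Forsythe median
centring available), a Welch unequal-variance t-test on per-subject
single-value variances, and an analysis of means of per-event standard
deviations with decision limits
$\bar{\bar s} \pm h\, s_p \sqrt{(k-1)/(kn)}$, where $h$ is the
Bonferroni-adjusted two-sided t quantile $t_{1-\alpha/2k,\,df}$ — a
standard, auditable stand-in for Nelson's exact tables, since the original
analysis names no variant. Variance is computed on raw $\Delta Z$ (ohms²)
for these analyses; a normalized-map variant is obtained by passing
$n\Delta Z$ values instead. Repeated-measures mixed models are deliberately
not re-implemented: `export_long_format()` writes the tidy long table any
external statistics package needs to refit them.

**Power analysis.** `paired_sample_size()` iterates the exact noncentral-t
power of a paired t-test; with the design inputs (0.003 V expected
difference, 0.002 V standard deviation, α = 0.05, power 0.95, two-sided) it
returns n = 8. The normal approximation does not reproduce this n at small
samples, which is why the t correction is used.

## What a green test does and does not establish

The simulator emulates the *statistical structure* the analysis assumes —
sector-localized responses of either sign, elastance-driven ICP, drift,
noise, artifacts, per-subject heterogeneity. It does not emulate real
physiology: no pulsatile or respiratory ICP components, no blood diffusion
beyond the uniform tracking fraction, no edema carry-over between phases, no
electrode-tissue interface dynamics beyond settling. Green property tests
therefore establish that the pipeline correctly recovers what the model
world contains (signs, locations, orderings, crossings) at realistic noise —
not that in vivo effect sizes or p-values are reproduced. The original
in vivo statistics (Pearson r of 0.803 vs 0.098, the mixed-model and Welch
p-values, the 44.1 Ω ANOM limit, brain volumes) depend on real recordings
and are intentionally out of numeric scope; their *generating procedures*
are what the tests exercise.

## Numerical choices and degenerate inputs

- Ties in slot selection go to the earlier slot; ties in the classifier are
  resolved by bulk isolation, then deviation, as above.
- `discriminatory_index` returns NA below a 0.1 mmHg pressure response
  rather than dividing by near-zero.
- `welch_t` with two zero-variance groups returns t = 0, p = 1 when means
  agree (0 otherwise, p = 0); `levene_test` with all-degenerate groups
  returns W = 0, p = 1.
- Single-subject cohorts skip the between-subject Welch and ANOM summaries
  (returned as NA/NULL) instead of erroring mid-pipeline.
- All simulator randomness flows through one scenario seed
  (`withr::with_seed`), and per-subject seeds derive from the master seed by
  a fixed counter scheme, so cohorts are bit-reproducible and extensible.
- Recording bundles are plain CSV/JSON (one directory per recording) with a
  versioned schema field; doubles round-trip at full precision.

## Known limitations

- The angular sensitivity kernel and focal gain are original modelling
  choices; absolute detection volumes in the simulated world (≈0.8–0.9 mL
  at the default mean-channel gain) are model properties, not predictions of
  in vivo sensitivity.
- Artifact detection during stepped phases is conservative: a genuine
  artifact landing within one detector window of a volume step is attributed
  to the protocol and missed.
- The step detector's recovery rule compares medians against the pre-step
  level; slow global signal ramps concurrent with an artifact can delay
  nominal recovery and over-mask (a conservative failure mode).
- Config parsing accepts JSON or R lists; TOML/YAML front-ends would need an
  additional parser dependency.
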