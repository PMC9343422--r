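---
title: "Methods: quantifying head-trunk segmentation from multi-sensor sway accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying head-trunk segmentation from multi-sensor sway accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaysync)
```

## The problem and the model

During quiet standing the body is never still: every point of the head and
trunk oscillates with small accelerations. Where two neighbouring points
belong to one effectively rigid segment, their acceleration waveforms are
nearly identical; where a compliant "link" (a functional joint) lies between
them, the waveforms decouple. `swaysync` operationalizes this idea for a
cranio-caudal chain of tri-axial accelerometers (22 by default, occiput to
sacrum) measured in two horizontal directions, medial-lateral (ML) and
anterior-posterior (AP).

For each sensor pair $(n, m)$ and direction $j$, two statistics are computed
from the preprocessed acceleration series:

* **Acceleration correlation (AC)** — the Pearson correlation of the two
  series.
* **Signed phase-synchronization index** $V_{nm}$ — each series is given an
  instantaneous phase $\phi_n(t)$ via the Hilbert-transform analytic signal;
  the phase differences are averaged on the unit circle,
  $$v_{nm} = \frac{1}{T}\sum_{t} \exp\!\big\{ i[\phi_m(t) - \phi_n(t)]\big\},
  \qquad \theta_{nm} = \arg v_{nm},$$
  and collapsed to
  $$V_{nm} = |v_{nm}|\,\frac{\cos\theta_{nm}}{|\cos\theta_{nm}|}.$$
  $|v_{nm}|$ is the familiar phase locking value (PLV); the cosine sign
  distinguishes in-phase ($V \to +1$) from anti-phase ($V \to -1$) locking,
  and $V \approx 0$ means weak locking of either kind. $\phi_m$ is the more
  caudal sensor, so a positive $\theta$ means the caudal sensor leads.

Per-subject values are averaged over trials, then across subjects (mean and
$n-1$ SD), giving the group quantities AAC and APLV. Group means are banded
into categories — very strong ($\ge 0.8$), strong ($[0.6, 0.8)$), moderate
($[0.4, 0.6)$), weak ($< 0.4$) — and the ordered adjacent-pair profile is
scanned for *coherent runs* (every internal pair at or above the high
threshold, default 0.6) and *link sites* (pairs below the low threshold,
default 0.4). A two-way repeated-measures ANOVA (condition x sensor pair)
with Bonferroni-corrected post hoc paired $t$-tests compares eyes-open (EO)
and eyes-closed (EC) standing.

## Preprocessing choices

The preprocessing stage makes four concrete numerical choices, none of which
is dictated by the physics and all of which are configurable:

* **Initial-posture correction.** Each sensor's orientation is estimated
  from the first second of the trial (assumed quasi-static): the window-mean
  acceleration is taken as the gravity direction and the *minimal-angle*
  rotation mapping it onto the world vertical is applied. Rotation about the
  vertical axis is unobservable from gravity alone; the nominal mounting of
  the sensor defines ML and AP. A window-mean norm below $0.5\,g$ aborts
  with an error, since the static assumption has then clearly failed.
  Gravity is taken as 9.81 m/s².
* **Low-pass filtering.** A 4th-order Butterworth at 20 Hz, applied
  forward-backward (zero phase). Zero-phase filtering matters here: a causal
  filter would add a frequency-dependent phase lag that the synchronization
  index would mistake for physiology. The effective magnitude response is
  the square of the single-pass response; the test-suite checks it against
  the closed form $1/(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2\,\cdot\,4})$.
  Because no DSP package is assumed, the bilinear-transform design and the
  forward-backward pass (odd-reflection padding, steady-state initial
  conditions) are implemented in the package and validated against that
  closed form.
* **De-meaning.** Horizontal series are de-meaned after filtering; a DC
  offset would corrupt the analytic-signal phase.
* **Edge trim.** The analytic signal is distorted near the series ends
  (FFT periodicity); 0.5 s is discarded at each end of the phase series
  before averaging, uniformly for all sensors, and the correlation is
  computed on the same trimmed window so both statistics describe identical
  data. The trim is a parameter of `all_pairs_sync()`.

**Degenerate sign rule.** $\cos\theta/|\cos\theta|$ is undefined at
$\theta = \pm\pi/2$. When $|\cos\theta| < 10^{-12}$ the sign is defined as
$+1$ and the result is flagged (`degenerate` column). The case has measure
zero in practice but a deterministic, flagged rule keeps the pipeline total.

**Category boundaries.** The verbal definitions of the four bands are
ambiguous exactly at 0.4, 0.6 and 0.8; the package closes each band at its
lower edge ($0.80 \to$ VS, $0.60 \to$ S, $0.40 \to$ M), the only rule
consistent with all 168 published boundary cells bundled in
`reference_group_stats()` (the test-suite verifies every cell).

**Run conventions.** A coherent run is any maximal window whose internal
adjacent pairs all qualify; a single qualifying pair is reported as a
two-sensor run. Values inside the open interval (low, high) influence
nothing — a property the tests enforce by perturbation.

## The synthetic world

No raw multi-sensor recordings of this kind are publicly deposited, so the
package ships a seeded generator (`sway_spec()`, `generate_recording()`)
that emulates the measurement: sensors partitioned into contiguous rigid
clusters, each cluster driven by one band-limited Gaussian source, plus
optional global coupling, per-sensor white noise, gravity and static tilt.
Its defaults are fixed once and state the world the validation runs in:

| parameter | default | rationale |
|---|---|---|
| sensors, rate, duration | 22, 1000 Hz, 20 s | the measurement setup being emulated |
| source band | 0.1-3 Hz | typical postural-sway band, far below the 20 Hz cutoff |
| source amplitude | 0.05 m/s² | realistic trunk sway acceleration RMS in quiet standing |
| noise SD | 0.005 m/s² | power SNR 100; well above the recovery threshold (SNR 10) |
| polarity / lag | +1 / 0 s | anti-phase as exact sign inversion, lag as circular shift, giving closed-form expected V |
| tilt | 0 rad | set per sensor (pitch about ML) to exercise the posture correction |

Sources are white Gaussian noise restricted to the band by zeroing Fourier
coefficients (so in-band spectral mass is ~100% and the DC bin is exactly
zero). Anti-phase sign inversion yields $V = -1$ exactly in the noiseless
limit; a lag $\tau$ of a narrow-band source at centre frequency $f$ shifts
$\theta$ by $\approx 2\pi f \tau$, which the tests verify.

**What the generator does not emulate** — and therefore what a green
recovery test does *not* establish: inverted-pendulum dynamics, muscle
activity, non-stationarity within a trial, inter-subject anatomy, sensor
drift or skin-motion artifact. The generator validates the *estimator*, not
the physiology.

**A calibrated fact about the null.** For two *independent* band-limited
sources the phase series are strongly autocorrelated, so the null PLV is
governed by the number of effectively independent samples (roughly duration
x bandwidth, here ~60), not by the raw sample count $T$. Monte Carlo gives
$E|v| \approx 0.11$ at the default settings — an order of magnitude above
the white-phase Rayleigh level $\sqrt{\pi/(4T)} \approx 0.006$, yet
comfortably below the 0.4 link threshold, which is why link detection works.
The Rayleigh law and the $T^{-1/2}$ scaling are verified where they actually
apply: on i.i.d. uniform phase series.

## The ANOVA error model

For $s$ subjects, 2 conditions and 21 pairs, the default model is the
standard fully-within-subject partition: each effect is tested against its
own interaction with subjects, giving $F(1, s-1)$ for condition,
$F(20, 20(s-1))$ for pair and $F(20, 20(s-1))$ for the interaction — at
$s = 10$: $F(1, 9)$ and $F(20, 180)$. Published analyses of this design
sometimes report other denominator degrees of freedom (e.g. 189, consistent
with a subject x pair blocking term); since that model cannot be
reconstructed unambiguously, the package provides the defensible
alternative `error_term = "pooled"` (the three subject-interaction terms
pooled, $df = 41(s-1)$) and labels its output, rather than guessing a
single truth. No sphericity correction is applied by default. The
implementation is plain balanced sums-of-squares arithmetic, cross-checked
in the tests against `stats::aov` with an `Error(subject/(condition*pair))`
stratum and calibrated under a 1000-replicate null simulation at the
$10 \times 2 \times 21$ design size.

**APLV averages the signed index.** The group synchronization table
aggregates $V$ (not $|v|$) by default, because the categories treat
anti-phase locking as meaningful and a signed mean near zero is the honest
summary of mixed-phase pairs. Strict magnitude averaging is available via
`group_mean_sd(..., metric = "plv")`.

## Worked example

```{r example}
spec <- sway_spec(clusters = list(1:8, 9:12, 13:22), seed = 42)
ground_truth_segmentation(spec)$link_pairs

rec <- generate_recording(spec)
pre <- preprocess_recording(rec)
sync <- all_pairs_sync(pre, pairs = "adjacent")
ml <- sync[sync$direction == "ML", ]
find_clusters(ml$V)
```

The planted boundaries (8,9) and (12,13) reappear as link sites; all other
adjacent pairs form coherent runs.

## Known limitations

* The heading ambiguity means ML/AP axes are only as good as the nominal
  mounting; a sensor rotated about its vertical axis mixes ML into AP
  undetectably.
* The orientation estimate inherits any sway contamination of the first
  second; with the default amplitudes the induced error is well under 1°,
  but violent initial movement would bias it.
* PLV-type statistics on band-limited signals have a broad null
  distribution (see above); single-trial values near 0.1-0.2 are not
  evidence of coupling.
* The ANOVA assumes balance and, by default, sphericity; a
  Greenhouse-Geisser-style correction is deliberately not applied, to match
  the conventional reporting of this design.
```
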