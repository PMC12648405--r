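---
title: "Distance-resolved bipolar re-referencing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-resolved bipolar re-referencing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bprr)
```

## The problem

Intracranial EEG is recorded referentially — every contact against one shared
reference — and then commonly re-referenced in bipolar fashion (BPRR): one
contact's trace is subtracted from a neighbour's. The derived channel
approximates the first spatial derivative of the field along the pair axis,
so what it measures depends on the *physical separation* of the two contacts.
Manufactured pitches vary (4 mm high-density grids, 5 mm depth probes, 10 mm
strips), and pairs formed across a 3D implant span anything from 2 to beyond
60 mm. `bprr` quantifies how that separation reshapes spectral power,
task-related high-gamma contrasts, and line-length-based detection of
interictal epileptiform discharges (IEDs), and ships a synthetic field
generator whose bipolar-to-referential power ratios are known in closed form.

## The physical model behind the generator

For a plane travelling wave of temporal frequency $f$ propagating at speed
$v$, the spatial wavelength is $\lambda(f) = v/f$. Two contacts separated by
$d$ along the propagation axis see the wave with a spatial phase offset
$2\pi d/\lambda$, and the difference signal has power

$$ R(d) \;=\; 4\sin^2\!\left(\frac{\pi d \cos\theta}{\lambda}\right) $$

relative to a single contact, with $\theta$ the angle between pair axis and
propagation (`analytic_pair_power_ratio()`). Landmarks: $R = 0$ at $d = 0$
(common-mode cancellation), $R = 1$ at $d\cos\theta = \lambda/6$ (the
*reversal point*, where the bipolar channel neither attenuates nor amplifies),
and $R = 4$ at half a wavelength. Averaging over uniformly distributed
in-plane orientations — what an omnidirectional distance bin does — gives
$2\,(1 - J_0(2\pi d/\lambda))$ (`analytic_bin_power_ratio()`).

With $v = 0.72$ m/s, a 48 mm wavelength (i.e. a 15 Hz wave) reverses at
exactly 8 mm, and a fixed 4 mm pair crosses from attenuation to gain at
30 Hz — the two headline landmarks `scripts/acceptance.R` recomputes.

Aperiodic (non-oscillatory) activity is modelled as a $1/f$ field whose
inter-contact correlation decays as $\exp(-d/\ell)$. The difference of two
such signals has relative power $2\,(1 - e^{-d/\ell})$
(`analytic_aperiodic_power_ratio()`): $+26\%$ at $d = \ell = 4$ mm and
$\to +100\%$ (doubled variance) for $d \gg \ell$.

## The reference configuration

`reference_field_config()` encodes the default study conditions:

* **Travelling-wave continuum, 2–30 Hz.** Components every 0.5 Hz, each a
  plane wave with $\lambda(f) = v/f$ ($v = 0.72$ m/s), random bearing and
  phase, and amplitudes following $1/f$, carrying $\approx 40\%$ of
  low-frequency power. A continuum rather than a handful of tones is used
  because real low-frequency LFP power is broadband: with discrete tones
  only, frequencies between the peaks would carry no low-frequency power at
  all and the distance–frequency map would be undefined there.
* **Discrete wave peaks** at 4, 8, 12, 20 and 28 Hz, sized as modest bumps on
  the continuum.
* **Broadband aperiodic field** with density $K/f$ ($K = 100\ \mu V^2$·Hz at
  1 Hz, giving realistic tens-of-µV signals), coherence length
  $\ell = 4$ mm, spanning the whole band; above 30 Hz it is the only neural
  component.
* **Common-mode artifact**: 60/120/180/240 Hz mains tones (large, since the
  notch stage removes them) and two narrow reference-contact peaks above
  75 Hz (85 and 105 Hz) at 1 µV. The peaks are deliberately small so they
  do not dominate the high-frequency percent-change map; a dedicated test
  verifies that any common-mode component cancels exactly under BPRR.

The 40/60 wave/aperiodic split at low frequencies is the one genuinely free
choice and is bounded on both sides by the map's qualitative structure:
below $\approx\!20\%$ aperiodic share, pure plane waves of 2–4 Hz
($\lambda = 180$–360 mm) would stay *attenuated* out to 30–60 mm and the
map could not turn positive at every frequency beyond 16 mm; above
$\approx\!55\%$, the aperiodic gain would already win at 4 mm and low
frequencies would not be attenuated there. The midpoint 40% satisfies both
regimes with margin, as the bin-averaged closed forms show.

With this mixture the full pipeline reproduces the crescent-shaped
distance–frequency relation: percent change at the 4 mm bin is negative for
all $f \le 20$ Hz (about $-25\%$ to $-5\%$), positive for all $f > 30$ Hz
(about $+25\%$), and positive at every frequency from the 16 mm bin outward
(about $+25\%$ to $+100\%$).

## Signal processing choices

* **Anti-aliasing and resampling.** Zero-phase (forward–backward)
  Butterworth low-pass below 255 Hz, order 4 per pass, with odd-reflection
  end padding to suppress edge transients; then frequency-domain (ideal
  low-pass) interpolation from 3052 Hz to 512 Hz, which handles the
  non-integer rate ratio exactly and preserves DC.
* **Notch.** Zero-phase 2nd-order Butterworth band-stops, 2 Hz wide, at 60,
  120, 180 and 240 Hz. Measured: $>$ 20 dB at the notch, $<$ 1 dB at
  $\pm 10$ Hz.
* **Windows.** Consecutive non-overlapping 1 s windows from $t = 0$; windows
  overlapping IED or artifact annotations are discarded; stimulus-overlapping
  windows are labelled for the task contrast. IED windows are 1 s re-centred
  on the sample with the maximum absolute first difference across channels
  (ties broken earliest).
* **Multitaper spectra.** Slepian tapers computed from the standard
  symmetric tridiagonal eigenproblem (no multitaper package is part of the
  dependency set, so the tapers are built in-package and validated against
  white-noise/Parseval and pure-tone oracles). Defaults: 1 s windows,
  time–bandwidth 3, 5 tapers ($\approx\pm 3$ Hz smoothing), demeaned
  windows, one-sided density on the 2–200 Hz, 1 Hz grid. Averaging over
  windows and tapers is arithmetic on the linear power scale. Pair spectra
  are computed from the channel-wise tapered FFTs by linearity (the
  transform of a difference is the difference of transforms), which avoids
  materialising tens of thousands of bipolar traces; equality with the
  direct route is asserted in the tests.

## Map construction

Pairs are enumerated either linear-ordinally (within depth/strip lines and
grid rows; distance = skip × pitch, skips 1–5 by default) or
omnidirectionally (all within-component pairs at 3D Euclidean distance).
Distances are binned half-open $[low, low+2)$ mm over $[2, 60]$ mm; bins
with fewer than 5 pairs are reported as missing, and on large grids pairs
are subsampled to a per-bin cap (default 250) with a fixed seed, which is
ample for bin means.

Two maps are built per run:

* `sqrt_zscore_map()`: bin-mean of $\sqrt{\text{power}}$, then each
  frequency row z-scored across populated bins (population SD, so two bins
  give exactly $\mp 1$).
* `percent_change_map()`: per pair,
  $100\,(P_{bip} - \bar P_{ref})/\bar P_{ref}$ with $\bar P_{ref}$ the mean
  of the two contributing referential curves, averaged within bins.
  Positive values mean the bipolar derivation carries more power. The
  percent change is computed on linear power by default: on that scale the
  independent-noise limit is exactly $+100\%$ and the $\ell = 4$ mm
  aperiodic field gives $+26\%$ at 4 mm; a `scale = "sqrt"` switch compares
  amplitude-like curves instead, and `legacy_sign` reproduces the opposite
  orientation convention.

Cross-subject band summaries (`band_summary_tests()`) use subject-level
paired Wilcoxon signed-rank tests of band-mean bipolar vs referential power
per band × ordinal distance, BH-FDR corrected across all tests; effect sizes
are matched rank-biserial correlations. Curves from different subjects are
made comparable by `rebase_spectra()`: all spectra go to log10 power and the
median over 2–10 Hz of the subject's electrode-averaged referential
log-spectrum is subtracted — an offset on the log scale, so every
between-curve power difference is preserved.

## Statistics

The shared permutation engine (`cluster_perm_test()`) compares two groups of
observations over a cell grid: pooled-variance t per cell, cluster-forming
threshold two-sided $t$ at $\alpha_{cell} = 0.05$, clusters as 4-connected
components (frequency × distance grids) or contiguous runs (time), cluster
mass = sum of t, and significance against the permutation null of the
maximum absolute cluster mass (default 1000 label permutations, all seeded
and bit-reproducible). These defaults are the field's common choices and are
config-exposed. Type-I calibration is asserted in the tests: the fraction of
null simulations with any significant cluster lies in $[0.02, 0.09]$ at
$\alpha = 0.05$ for both the grid and the time-series engines.

For the task contrast, per-window bin-averaged log10 power is normalised by
a *fixed* per-frequency affine (mean and population SD pooled over bins and
windows) before the stimulus-minus-baseline difference. Normalising each
window by its own bin statistics would delete any distance-uniform condition
effect, and using only the grand mean map's SD degenerates when power is
flat across bins; pooling windows keeps the scale well defined in both
regimes. The 50–200 Hz average of the difference map per bin is the
high-gamma summary curve.

For the IED analysis, line-length transforms (instantaneous = per-sample
absolute first difference; windowed = centred moving sum over 100/40/20 ms,
partial windows flagged at the edges) feed channel-wise cluster permutation
tests of IED-centred vs baseline windows, with baseline windows subsampled
to match the IED count by default ("randomly drawn" matching; a flag uses
all). Channel-level p-values (the channel's largest-mass cluster against its
own permutation null) are BH-FDR corrected across channels within subject.
Extent metrics: per-channel significant duration (samples × 1000/fs ms),
mean width over significant channels (a `max` alternative is available), and
the significant-channel count. High- vs low-density schemes (same base
electrodes, partners one vs two pitches away) are compared per metric with
paired Wilcoxon signed-rank tests at the Bonferroni-adjusted threshold
$0.05/4 = 0.0125$ across the four line-length conditions. Participants enter
the IED analysis only with at least 50 IED windows.

One calibration fact is worth stating because it bounds what any
implementation can achieve: with five true and three null channels under
BH-FDR at $q = 0.05$, a perfectly calibrated engine still admits a null
channel into the rejection set in roughly 10% of runs (null channel-level
p-values are uniform by construction — measured 0.040 at the 0.0375
threshold in 300 simulations). Exact-recovery rates around 90% are therefore
the *ceiling*, not a shortfall of the detector.

## Problem sizes used in the shipped checks

The reference pipeline run used by the test suite simulates a 12 × 12 grid
(4 mm pitch, 144 contacts) for 60 s at 3052 Hz, downsampled to 512 Hz,
with omnidirectional pairs subsampled to 250 per 2 mm bin; this yields the
full 199 × 30 distance–frequency map and reproduces the crescent pattern.
The oracle-equivalence sweep uses 21-contact lines (2–40 mm separations) at
four wavelengths for 60 s each; calibration suites use 200 null simulations
per engine; recovery suites use 50 runs of 20 + 20 windows. These sizes were
chosen so the whole suite runs comfortably on a laptop while keeping every
Monte-Carlo tolerance well inside its expected sampling error.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analyses rely on —
distance-dependent coherence of low-frequency oscillations, distance-flat
doubling of independent high-frequency activity, common-mode artifact,
spike-and-wave transients with a spatial footprint, band-limited task
gains — with known ground truth. It does not model volume conduction,
cortical folding, white/gray matter differences, region-specific spectra, or
non-stationarity, and the travelling-wave mechanism is one concrete
instantiation of the distance–frequency relation, not a claim about its
unique physiological origin. Passing tests therefore demonstrate that the
*pipeline* measures what it claims under controlled conditions, not that
real recordings obey the generator's simplifications.

## Known limitations

* EDF input is not parsed; recordings enter as in-memory matrices or as
  flat 32-bit binary with a JSON sidecar (`read_recording_bin()`).
* The linear-ordinal scheme takes grid rows from the electrode table's
  `row_id` (manufacturer layout) and never infers them from coordinates.
* Anatomical stratification is out of scope; the electrode table's `subset`
  flag stands in for region membership (e.g. superior temporal gyrus).
* Cluster-permutation defaults (threshold, adjacency, statistic, 1000
  permutations) are conventional, not derived; all are arguments.
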