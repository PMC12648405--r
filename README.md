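# bprr — distance-resolved bipolar re-referencing for intracranial EEG

Bipolar re-referencing (BPRR) subtracts one intracranial electrode's
referential trace from a neighbour's. The derived channel approximates the
first spatial derivative of the cortical field, so *how far apart* the two
contacts are decides what the channel measures: low-frequency oscillations
with long spatial wavelengths are suppressed at short separations, while
spatially incoherent high-frequency activity is amplified at every
separation. `bprr` is for iEEG researchers and clinical neurophysiologists
who want to quantify these distance effects — to pick a bipolar distance
for a frequency-band biomarker, to check how a montage reshapes task-related
high gamma, or to compare epileptiform-discharge detection between electrode
densities.

## The model at the core

For a plane travelling wave with temporal frequency *f*, propagation speed
*v* and spatial wavelength λ(*f*) = *v*/*f*, a bipolar pair separated by *d*
along the propagation axis carries

    P_bip / P_ref = 4 sin²(π d cosθ / λ)

times the single-electrode power. This is 0 at *d* = 0 (common-mode
cancellation), **1 at *d* = λ/6** — the reversal point where bipolar equals
referential — and 4 at half a wavelength. Orientation-averaged over a
distance bin the ratio becomes 2(1 − J₀(2π*d*/λ)). Aperiodic activity with
spatial coherence exp(−*d*/ℓ) instead follows 2(1 − e^(−*d*/ℓ)), rising to
+100% (doubled variance) for *d* ≫ ℓ. With *v* = 0.72 m/s these closed
forms put the low-frequency reversal at **8 mm** and the 4 mm pair's
attenuation-to-gain transition at **30 Hz**.

The package implements, as testable modules:

* electrode geometry: linear-ordinal and omnidirectional (3D Euclidean)
  bipolar pair sets, 2 mm distance binning over 2–60 mm;
* preprocessing: zero-phase anti-alias filtering, 3052→512 Hz resampling,
  mains notches, 1 s window parsing and slope-centred IED windows;
* Slepian multitaper spectra (2–200 Hz, 1 Hz grid) and referential
  rebasing;
* distance–frequency maps: z-scored √power and percent change from the
  referential mean, plus band-level Wilcoxon/FDR summaries;
* stimulus-vs-baseline contrasts with cluster-based permutation tests and
  a 50–200 Hz high-gamma metric;
* line-length IED analysis with high- vs low-density montage subsampling;
* a synthetic field generator (travelling-wave continuum + spatially
  coherent aperiodic field + common-mode artifact + injectable IEDs and
  task gains) with the closed-form oracles above;
* `run_pipeline()`, a seeded end-to-end driver writing TSV/JSON outputs and
  a run manifest (thin CLI wrapper in `inst/scripts/bprr`).

## Worked example

```r
library(bprr)

find_reversal_distance(lambda_mm = 48)$distance_mm     # 8.00
find_transition_frequency(d_mm = 4)$frequency_hz       # 30.0
round(analytic_pair_power_ratio(c(2, 4, 8, 12, 16, 24), 48), 3)
#> 0.068 0.268 1.000 2.000 3.000 4.000

arr <- make_geometry("grid12x12")                # 144 contacts, 4 mm pitch
rec <- simulate_field(arr, reference_field_config(), duration_s = 10, seed = 1)
rec
#> <ieeg_recording> 144 channels x 30520 samples @ 3052 Hz (10.0 s)

w <- parse_baseline_windows(notch_line_noise(lowpass_downsample(rec)))
#> <ieeg_windows> 10 windows (baseline:10) | 144 channels x 512 samples @ 512 Hz

pairs <- subsample_pairs(
  bin_pairs_by_distance(enumerate_omnidirectional_pairs(arr)), 100, seed = 1)
pc <- percent_change_map(bipolar_psd(w, pairs), multitaper_psd(w), pairs)
round(pc$values["10", c("5", "17", "29")], 1)    # 10 Hz row
#>     5    17    29
#> -18.1  54.2 103.5
round(pc$values["80", c("5", "17", "29")], 1)    # 80 Hz row
#>     5    17    29
#>  39.5  97.7 102.2
```

Read: at the 4–6 mm bin a 10 Hz oscillation *loses* ~18% power under BPRR
while 80 Hz activity *gains* ~40%; by 16–18 mm every frequency is enhanced,
and by ~28 mm both approach the independent-signal limit (+100%). That is
the crescent-shaped distance–frequency relation, here on a 10 s
simulation; `run_pipeline(pipeline_config(), "out/run1")` produces the full
map, its pair-count companion and a manifest from a 60 s run.

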