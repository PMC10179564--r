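---
title: "Methods: feature relevance selection for upper-limb kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature relevance selection for upper-limb kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfresh)
```

kinfresh implements a univariate feature-relevance pipeline for
three-dimensional upper-limb marker trajectories recorded during
reach-and-lift movements, together with a cohort simulator that makes every
stage testable without clinical recordings. This vignette documents the
model, the numerical conventions, and the design decisions; the README shows
a worked end-to-end example.

## The analysis pipeline

A *recording* is a fixed-rate capture of four markers along the arm's
kinematic chain — index fingernail (FN), lateral epicondyle (LEP), middle of
the humerus (MPH), acromion (ACR) — each with x/y/z coordinates in metres.
Each recording carries a class label: `G0` (non-affected post-stroke limb),
`G1` (affected limb), `G2` (healthy-control limb).

The stages, in order:

1. **Side unification** (`reflect_to_common_side`). Right-limb recordings
   are mirrored through the sagittal (yz) plane by negating x, so both limbs
   share one coordinate convention. Reflection precedes differentiation so
   velocity and acceleration signs stay consistent; reflecting after min–max
   normalisation would be a no-op or an inversion ambiguity.
2. **Cropping** (`crop_to_lift`). The activity window is detected on the FN
   marker's vertical (z) series: the threshold is 10% of the FNz range, and
   the window runs from the first to the last sample exceeding the starting
   value plus the threshold.
3. **Series derivation** (`derive_series`). Per marker: trajectory
   (`Mx,My,Mz`), displacement from the first cropped sample
   (`Mdx,Mdy,Mdz`) plus its Euclidean module `MD`, velocity
   (`Mvx,Mvy,Mvz`) plus speed `MV`, acceleration (`Max,May,Maz`) plus its
   module `MA` — 15 series per marker, 60 per recording. Displacement is
   cumulative from the window start (frame-to-frame differences would
   duplicate velocity up to a constant), so `MD` reads as distance from
   start. Velocity uses central first differences scaled by the sampling
   rate, one-sided at the ends; acceleration uses central second
   differences scaled by rate squared, with the end values equal to the
   one-sided three-point stencil.
4. **Normalisation** (`normalize_minmax`). Each of the 60 series is
   independently mapped to [0, 1]; constant series map to zeros and are
   flagged. Downstream results are therefore invariant to positive affine
   maps of the raw coordinates.
5. **Feature extraction** (`extract_features`, `build_feature_matrix`).
   Every series is mapped to a catalogue of scalar features (42 in the core
   catalogue; `feature_catalog(794)` grows it to the reference
   dimensionality, giving 60 × 794 = 47,640 values per recording). Features
   are typed real or binary; undefined cases yield NaN and are flagged, not
   dropped.
6. **Relevance selection** (`select_relevant`, `one_vs_rest_common`). The
   three-class problem is decomposed into three one-vs-rest binary
   problems. Within each problem every feature column is tested
   individually — Mann–Whitney U for real-valued columns, two-sided Fisher
   exact for binary columns — and the Benjamini–Yekutieli step-up procedure
   controls the false discovery rate at q = 0.05 across that problem's
   p-vector. Features significant in all three problems form the *common*
   set.
7. **Reporting** (`aggregate_counts`, `report_wide`). Common features are
   counted by marker, movement axis (x/y/z/module) and signal domain
   (trajectory/displacement/velocity/acceleration). The bundled fixture
   `published_counts_path()` carries a published study's grid of 1,004
   common features and reproduces its marginals exactly.

## Numerical conventions (pinned in tests)

* **Mann–Whitney U**: exact null distribution (via `stats::pwilcox`) when
  the pooled size is ≤ 12 and there are no ties; the two-sided exact p is
  twice the lower-tail probability of the smaller U (the null distribution
  of U is symmetric). Otherwise the normal approximation with midrank tie
  correction and 0.5 continuity correction. Verified against full label
  enumeration, a permutation oracle, and `stats::wilcox.test`.
* **Fisher exact (two-sided)**: point-probability method — sum of all
  hypergeometric point probabilities not exceeding that of the observed
  table (relative tolerance 1e-7), matching `stats::fisher.test`.
* **Benjamini–Yekutieli**: with m tests and c(m) = Σ 1/i, reject the k*
  smallest p-values where k* is the largest k with p(k) ≤ k·q/(m·c(m));
  step-up, so every rank below k* is rejected. BY rejections are provably
  nested inside Benjamini–Hochberg rejections inside raw thresholding.
* **Feature moments** use population (biased) variance; autocorrelation
  divides the lag-l autocovariance by n·Var_pop (the `stats::acf`
  convention, e.g. 0.25 for `[1,2,3,4]` at lag 1); quantiles are type 7;
  location-of-extremum features are relative positions in [0, 1]; FFT
  features are coefficient magnitudes at integer frequencies.
* All seeding flows from one master seed, fanned out to per-recording seeds
  by a stable string hash of the recording id, so subsetting a cohort never
  shifts another recording's noise, and reruns are bit-identical.

## The cohort simulator

`simulate_cohort` emulates the lifting protocol the analysis targets:
35 post-stroke participants contribute three recordings of each limb
(non-affected → G0, affected → G1) and 19 controls contribute three of both
limbs (G2), reproducing the 105 / 105 / 114 recording counts.

Each coordinate follows a minimal-jerk rise-and-return
(x(τ) = x₀ + (x_f − x₀)(10τ³ − 15τ⁴ + 6τ⁵)), the standard model of
point-to-point reaching with its bell-shaped velocity profile (peak velocity
1.875 for a unit move in unit time). Defaults and their rationale:

* 100 Hz capture, 2.5 s movement, 0.5 s rest padding on both sides (gives
  the cropping stage something to remove).
* Vertical excursion 0.5 m at the fingernail, tapering proximally
  (FN 1.0, LEP 0.7, MPH 0.4, ACR 0.15); axis weights z 1.0, y 0.4, x 0.1
  (vertical lift dominant, forward reach moderate, transverse small).
* Per-participant log-normal amplitude scale (sd 0.1), stable across that
  participant's recordings.
* Sensor noise sd 5e-5 m per sample and axis — the residual jitter scale of
  filtered optical marker capture. (Millimetre-scale noise would make the
  double-differenced acceleration of every recording pure noise at 100 Hz,
  because double-differencing amplifies white noise by rate².)
* Per-recording low-frequency motor variability (`shape_variability`,
  default 5% of each coordinate's excursion, three random 0.3–1.5 Hz
  components windowed to the movement, shared across markers). Repeated
  human reaches are never identical; without this term every normalised
  null trajectory would be the same curve plus sensor noise.

Class effects are injected per marker and axis: `amplitude_scale`
(hypometria), `submovement_count` (corrective submovements), and
`jerk_noise_sd` — a band-limited 8–12 Hz positional oscillation in the
physiological tremor band with per-recording random frequency and phase.
Because differentiation weights a tone at ω by ω (velocity) and ω²
(acceleration) while leaving low-frequency movement content dominant
elsewhere, tremor is predominantly an acceleration-domain signature — but
only once the acceleration domain reflects movement rather than the sensor
noise floor. The pipeline therefore exposes optional Savitzky–Golay
smoothing (`smoothing = TRUE`; cubic, 9-sample window) before
differentiation, the standard practice when derivative-domain statistics are
of interest. Against *unsmoothed white* noise, no positional signal can be
relatively more detectable in acceleration than in velocity: differentiation
scales the tone and the noise spectrum identically.

A related rank-mechanics property worth knowing when designing simulations:
a single strongly deviating class makes a feature significant in *all three*
one-vs-rest problems, because its deviation shifts every pooled-rest
comparison; conversely, the middle class of a monotone three-class ordering
can never separate from its pooled rest (its ranks split evenly). A
one-sided class effect is therefore the canonical way to produce a non-empty
common set.

## Problem sizes and runtime

The default simulated cohort (324 recordings, 60 series each, core
catalogue: 2,520 feature columns) runs end to end in under a minute on one
CPU. The full 794-feature catalogue (47,640 columns per recording) is a
configuration choice (`catalog_size = 794`) used for count reproduction;
the statistics layer is catalogue-agnostic.

## Limitations

The simulator is a minimal-jerk caricature: no joint-angle constraints, no
endpoint variability structure beyond the low-frequency term, no
trial-duration variability, and class effects are stylised. It exists to
make the pipeline's bookkeeping, statistics and attribution testable, not to
imitate clinical data. Real-data headline numbers (per-class significant
counts, the identity of common features) are data-dependent outcomes, not
reproducible targets.
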