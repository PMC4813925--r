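---
title: "Automatic carotid lumen detection with phase symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic carotid lumen detection with phase symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
set.seed(1)
```

```{r setup}
library(lumentrace)
```

## The detection model

Longitudinal B-mode images of the common carotid artery (CCA) show the
vessel as a dark, roughly horizontal band (the blood-filled lumen) bounded
above and below by bright wall interfaces. `lumentrace` localizes the lumen
*centerline* — one row per image column — in four stages:

1. **Phase-symmetry map.** The image is band-pass filtered to the scale
   range of plausible CCA diameters and decomposed with the monogenic
   (Riesz) signal into a locally even part `e` and an odd-energy part `o`.
   The dark-structure symmetry measure is

   `Sym = max(0, -e - o - T) / (A + eps)`, with `A = sqrt(e^2 + o^2)`.

   At the center of a dark band the local phase is an even trough (`e < 0`,
   `o ~ 0`), so `Sym -> 1`; at edges (odd phase) and on bright ridges
   (`e > 0`) it vanishes. Because only the *phase* enters, the measure is
   invariant to local brightness and contrast — the useful property on
   ultrasound, where gain varies across the field of view.

2. **Dynamic programming.** Among all 8-connected left-to-right paths,
   `dp_forward()` computes for every possible end row the maximal
   accumulated symmetry. Local maxima of this gain profile, detected with a
   Gaussian-derivative filter of scale `sigma_peak`, each yield one
   candidate centerline by backtracking.

3. **Feature gating.** Each candidate is scored with interpretable
   features — path-averaged symmetry, image intensity, and
   difference-of-offset-Gaussian (DooG) lumen-to-wall contrast
   `C+-(x) = G_off(x +- delta) - G_on(x)` — each in a line and a
   band-integrated variant. Features are normalized *per image* against the
   best candidate, and a one-dimensional logistic gate accepts candidates
   whose posterior reaches 0.5.

4. **Positional selection.** Among the accepted candidates the bottom-most
   is chosen: look-alike structures (jugular vein, sternocleidomastoid
   muscle) lie above the CCA, not below. If nothing is accepted, the
   highest-posterior candidate is returned flagged as a fallback.

## Parameters derive from population statistics

No scale parameter is tuned on data. The CCA diameter search range comes
from published population statistics of the CCA internal diameter via a
one-sided 99% normal interval, widened by the wall thicknesses:

```{r}
bounds <- estimate_diameter_bounds()
str(bounds)
params <- derive_parameters(bounds$d_min_mm, bounds$d_max_mm)
params
```

All remaining scales follow algebraically (values in mm; defaults assume
0.09 mm/px, images at other resolutions are resampled):

| parameter    | rule                  | role                                    |
|--------------|-----------------------|-----------------------------------------|
| `sigma_peak` | `d_min / 4`           | peak detection in the DP gain profile    |
| `sigma_on`   | `d_min / 2`           | on-center blur of the DooG contrast      |
| `sigma_off`  | `(d_max - d_min) / 4` | wall-region blur of the DooG contrast    |
| `delta`      | `(d_max + d_min) / 4` | centerline-to-wall offset of the DooG    |
| `rf`         | `d_min / 2`           | vertical radius of band features         |

## A worked example on a synthetic phantom

Real annotated carotid images cannot ship with the package, so it includes
a phantom generator that renders the geometry the detector relies on:

```{r phantom}
ph <- generate_phantom(phantom_spec(
  center_depth_mm = 18,
  distractor = list(diameter_mm = 4, gap_mm = 2, clean = TRUE),
  deep_band = list(gap_mm = 2.5, level = 0.1, noise_sd = 0.08),
  seed = 7))
plot_bmode(ph$image)
```

Candidate detection and the greedy symmetry baseline:

```{r candidates}
cands <- detect_candidates(ph$image)
cands[, c("candidate_id", "end_row", "gain", "mean_row")]
```

Train a gate on a small phantom bank and run the full detector:

```{r detect}
bank <- generate_dataset(12, seed = 42)
gate <- train_gate(bank, feature = "symmetry_line")
gate
det <- detect_lumen(ph$image, gate = gate, method = "proposed")
det
ggplot2::autoplot(det)
path_correct_fraction(det$rows, ph$annotation)
```

## What the phantoms emulate — and what they do not

Emulated, because the detector depends on it:

* dark lumen band of population-plausible diameter with layered
  intima/media/adventitia walls, over textured echogenic tissue;
* smooth centerline geometry (tilt, bow, low-frequency undulation) within
  the 1 px/column excursion of the path model;
* a jugular-like distractor *above* the artery — often rendered anechoic
  ("cleaner" than the artery), which is exactly the case where greedy
  maximum-symmetry selection fails and gating plus the bottom-most rule is
  needed;
* far-field attenuation below the artery (`deep_band`): the echo fades to
  a dark noisy floor. Its random phase and low amplitude give genuinely
  low symmetry, which is what makes below-artery candidates rejectable and
  provides negative training examples;
* plaques (protrusions of the far lumen-intima boundary), acoustic
  shadows, multiplicative speckle with intensity-dependent amplitude.

Not emulated: curved/branching vessels (bulb, bifurcation), out-of-plane
artifacts, reverberation, operator-dependent gain curves, and real speckle
statistics (fully developed speckle is Rayleigh-like; the package uses a
Gaussian model with `I^1/2` amplitude scaling). Results on phantoms
therefore validate the *mechanics* of the pipeline, not clinical
performance.

## Numerical choices

* **Stabilizer `eps`.** Set per image to `1e-3` times the 99th percentile
  of the local amplitude `A`, so the symmetry map is exactly invariant to
  affine intensity rescaling and low-amplitude round-off structure is not
  amplified. A fixed `eps` would break that invariance.
* **Noise floor `T`.** Defaults to 0 (phantoms are clean); raising it
  suppresses low-amplitude responses monotonically.
* **Riesz transfer.** Implemented in the frequency domain with the odd
  transfer pair proportional to `-i f / |f|`; the Nyquist rows/columns of
  even-sized transforms are zeroed to keep the transfers Hermitian so that
  real images produce exactly real outputs.
* **Boundary handling.** All filtering runs on mirror-padded images (pad =
  `d_max` in pixels), padded further to FFT-friendly sizes.
* **DP tie-breaks.** Gain ties prefer the straight predecessor, then the
  one above, then the one below — deterministic, smooth centerlines.
* **DooG margins.** Within `delta` rows of the bottom (for `C+`) / top
  (for `C-`) border the contrast is undefined; those samples are `NA`.
  Candidates lying *entirely* inside a margin are discarded; a candidate
  that only partially enters it is kept and its features are averaged over
  the valid samples (renormalized denominator).
* **SNR definition.** `snr_db = 10 log10(mean(I^2) / E[noise^2])`,
  evaluated *before* clipping to `[0, 1]`; the speckle model scales the
  Gaussian field by `I^1/2`, so its variance is calibrated through
  `mean(I)`.
* **Training on clean images only.** The gate is always fitted on
  noiseless candidates; per-image feature normalization is what lets the
  learned threshold transfer to noisy test conditions.

## Evaluation protocol

`run_experiment()` implements a repeated K-fold protocol on a phantom
bank: analysis of every image at every noise condition happens once; each
repetition re-splits the images into folds, refits the one-feature gates
on the noiseless training folds, and evaluates all selectors on the test
folds. Images whose candidate stage produced no acceptable path (in-lumen
fraction below 0.8) are excluded from the *selection* metric and reported
separately as the candidate-stage rate, so the two stages are assessed
independently. Defaults (5 folds, 5 repetitions, speckle noise from 30 to
-30 dB) keep runs short; all sizes are configurable through
`experiment_config()`.

```{r evaluate, eval = FALSE}
bank <- generate_dataset(200, seed = 2025)
report <- run_experiment(bank, experiment_config(seed = 7))
report
ggplot2::autoplot(report)
```

## Limitations

The detector returns exactly one centerline per image (by design — the
fallback flag marks unreliable outputs). Accuracy is reported against
synthetic ground truth; transferring the gate to a real scanner requires
retraining on annotated images via `fit_logistic()`/`train_gate()` and
checking the pixel size handling in `load_bmode()`. Extremely low SNR
(-20 dB and below) degrades the candidate stage itself, which no selection
strategy can repair.
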