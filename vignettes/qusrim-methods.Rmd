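---
title: "Methods: quantitative ultrasound of tumours and their surroundings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ultrasound of tumours and their surroundings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data model

Conventional B-mode reading of a breast lesion uses the tumour's visible
interior. Histology, however, shows that malignant growth remodels the
*surrounding* stroma — collagen deposition and realignment at the margin
(desmoplasia), infiltration beyond the sonographic border — and sonography
systematically underestimates tumour extent. The analysis implemented
here therefore treats two regions of interest per lesion symmetrically:
the **internal ROI** (inside the hand-drawn contour) and the **external
ROI**, a rim of fixed width (default 5 mm) around it, and asks which one
carries more class information.

The pipeline consumes raw RF frames (axial samples × scan lines, with
sampling frequency, line pitch and sound speed as metadata), a closed
contour polygon per lesion, and a class label. Envelope detection is
per-line Hilbert demodulation; the envelope is resampled axially onto an
isotropic grid at the line pitch (0.0745 mm by default) so that "4 pixels"
means the same distance in both directions. B-mode is
`20·log10(A / max A) + 100`, clipped to 20–100 dB.

## Estimators

Twelve parameters are estimated per 1 mm × 1 mm sliding window (13 × 13 px
at the default pitch; 92 % overlap by default):

* **Nakagami shape `NAK`** by the method of moments,
  `NAK = ⟨A²⟩² / σ²(A²)`. We use the population (divide-by-n) variance —
  the method-of-moments convention; at ≥ 169 samples per window the
  difference from n−1 is negligible. The estimator is exactly scale
  invariant, which is also why a depth-dependent system gain cancels in
  NAK but not in texture features.
* **Weighted entropy `ENT`**,
  `−Σᵢ w(Aᵢ)·P(Aᵢ)·log₂ P(Aᵢ)`, summed over the window's *samples*, with
  `w(Aᵢ) = Aᵢ/ΣA` and `P` estimated by a histogram over the window's own
  range. The sum-over-samples (rather than over bins) reading weights each
  bin by its occupancy as well as its amplitude; the source description is
  ambiguous between the two, and we implement the formula as literally
  written. The histogram uses 40 equal-width bins by default
  (configurable): of the order of the square root of the per-window sample
  count, the usual bias/variance compromise at this window size.
* **GLCM texture features** on the quantized B-mode (20 equal bins over
  20–100 dB, top edge closed): contrast, correlation, energy, homogeneity
  and variance from the co-occurrence matrix at a one-directional
  displacement of 0.3 mm (4 px). Vertical and horizontal displacements are
  kept as separate features (`*V`, `*H`) rather than averaged over four
  directions: the imaging point-spread function is strongly anisotropic,
  and the two directions demonstrably carry different information. Pairs
  are ordered (no transpose symmetrization) — one displacement per
  direction, no interior choices.

Degenerate windows (constant block for NAK; zero marginal SD for COR;
block smaller than the displacement) are marked invalid and excluded from
ROI averages rather than imputed.

## ROIs, windows, and averaging

The contour is rasterized with the even-odd rule on pixel centres. The rim
is built from the Euclidean distance transform of the internal mask:
pixels at distance in (0, rim width] — measured from the mask, which
coincides with the contour line up to one pixel. Optional exclusion masks
(e.g. a configurable-depth skin band for shallow lesions, or manually
flagged acoustic shadows) are subtracted from the rim; both are off by
default, matching the default behaviour of analysing everything.

A window belongs to an ROI iff its *centre pixel* is inside the ROI mask —
unbiased between the (smaller) interior and (larger) rim; a
minimum-overlap rule is available as an option. The per-lesion feature is
the unweighted mean of valid in-ROI window values pooled across the two
scan planes.

Reference-phantom correction: parametric maps of a homogeneous phantom
give, per parameter, a depth profile; the correction factor is
global-mean / row-mean, smoothed with a 5-row moving average, and maps are
corrected multiplicatively. Whether the original analysis corrected
multiplicatively or additively, and at envelope or parameter level, is not
stated; we correct parameter maps multiplicatively (system gain and beam
effects are multiplicative on amplitude) and expose an additive variant.
All twelve parameters are corrected, following the description that curves
were determined "for each" parameter.

## Classification

Scores come from k-NN (k = 4) with standardized Euclidean distance under
leave-one-out cross-validation. Standardization uses the training fold's
mean and SD only — the alternative (global standardization) is available,
but the default avoids leaking the held-out case into the metric; a
dedicated test verifies that an uninformative feature stays at AUC ≈ 0.5.
The malignancy score is the malignant fraction among the k neighbours
(neighbours tied with the k-th distance are all included and averaged),
giving 5 score levels at k = 4 — the minimal standard construction of a
ROC from a discrete classifier. AUC is the Mann–Whitney probability with
ties counted ½; the operating point maximizes Youden's J with ties broken
toward sensitivity (the threshold rule behind the original
sensitivity/specificity tables is unstated, so we fix a standard one and
do not attempt to match those cells). Group separation uses the two-sided
Wilcoxon rank-sum test: exact null for combined n ≤ 20 without ties,
tie-corrected normal approximation otherwise, with the usual
`*/**/***` classes at 0.05/0.01/0.001.

The exhaustive search evaluates every non-empty subset of a 12-feature
group — 4095 classifiers — with a Gray-code walk over subsets so each step
updates the precomputed per-feature distance matrices in O(n²). The
24-feature *combined* group would require 2²⁴ − 1 ≈ 1.7 × 10⁷ LOOCV
evaluations (~10¹² operations), which is not affordable on a single CPU;
`run_pipeline()` therefore searches the union of the parameters appearing
in the best internal and best external classifiers — the same structure as
the reported best combined classifier (two internal plus five external
parameters) — and this restriction is deliberate and documented.
`exhaustive_search()` itself is faithful for any group of ≤ 20 features.

## The synthetic world

No clinical data are deposited, so the generator creates the stated world
the tests run in:

* **Speckle synthesis is envelope-first**: one Nakagami amplitude and one
  uniform carrier phase are drawn per resolution cell (3 axial RF samples
  by default) and held within the cell; the RF sample is
  `A·cos(2πf_c t + φ)` at a 7.2 MHz carrier and 40 MHz sampling. This
  gives exact distributional control — the point of the generator — at the
  cost of physical realism: demodulation recovers the per-region shape
  parameter to within a few percent (the band-limiting of the analytic
  signal pulls extreme shape values slightly toward Rayleigh, e.g. a true
  1.4 reads ≈ 1.28), which is why region tests assert ordering and
  tolerance bands, not exact values.
* **Geometry**: elliptical lesions only, emitted as closed 64-vertex
  contours, so ROI construction has closed-form truth. The default
  acquisition grid is 1560 samples × 510 lines at 0.0745 mm pitch; the
  default lesion (semi-axes 7 × 5.8 mm) matches the cohort's mean
  equivalent diameter of ~12.7 mm.
* **Cohorts**: 59 benign / 57 malignant by default, two independent
  speckle realizations per lesion standing in for the longitudinal and
  transverse planes (the same ellipse in both — a simplification; real
  planes show different cross-sections). Per-lesion jitter (±10 % uniform,
  relative) on geometry and region statistics creates the between-lesion
  variance that makes classification non-trivial.
* **Class effects** are free parameters — the source reports no effect
  sizes, only boxplots — and are chosen once: the `rim` preset gives
  malignant lesions a rim with shape 0.7 and power 1.25 (benign rim:
  1.0/1.0, interiors identical at 0.8/0.45); the `interior` preset places
  the analogous shift inside instead. With 10 % jitter this yields a
  standardized separation of ~2–3 in the affected ROI's features — strong
  enough for stable direction-of-effect recovery at n = 116, far from
  degenerate in the unaffected ROI.
* A **reference phantom** generator imposes a strictly positive
  depth-gain profile on homogeneous speckle for correction-curve tests.

What a green test establishes: that the estimators, geometry, search and
comparison machinery recover what was put in, with the stated tolerances.
What it does not establish: anything about clinical effect sizes, scanner
physics (no diffraction, attenuation, or focusing is modelled beyond a
gain profile), or the transferability of the 5-mm rim to other probes.

## Numerical choices

* dB reference is the per-frame maximum (absolute gain is arbitrary).
* Axial resampling is linear, envelope before resampling.
* Window stride is `round(window_px · (1 − overlap))`, clamped to ≥ 1 px;
  windows lie fully inside the image.
* k-NN distance ties at rank k include all tied neighbours; ties in
  Youden's J break toward sensitivity; subset ranking ties break
  lexicographically on the subset name — all deterministic.
* Every generator consumes an explicit integer seed and restores the
  caller's RNG state; fixed seed ⇒ bit-identical output.
* Heavy simulations (the 59 + 57 cohort recovery tests) run at "reduced
  map resolution": a smaller scene (912 × 240 grid, 2.8 × 2.3 mm lesion)
  and non-overlapping windows. This changes the number of windows averaged
  per ROI, not the statistical structure.

## Known limitations

* The combined-group search restriction described above.
* Envelope-first synthesis does not emulate scatterer-convolution
  speckle; texture features on synthetic B-mode reflect the imposed
  statistics, not tissue micro-architecture.
* A single contour serves both planes of a synthetic lesion.
* Shadow regions must be flagged manually as exclusion masks; there is no
  automatic shadow or skin detection.
* `estimate_correction_curve()` assumes the phantom map and lesion maps
  share the window/depth grid (same acquisition geometry), as in the
  emulated study design.
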