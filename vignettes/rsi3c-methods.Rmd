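---
title: "Automated DWI-based tumor response assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated DWI-based tumor response assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsi3c)
```

This vignette documents the science inside `rsi3c`: the signal model, the
voxel classifier, the automatic sizing geometry, the endpoint statistics,
the synthetic phantom, and — because several of these steps admit more than
one defensible reading — the design choices the package commits to and why.

## The three-component signal model

Multi-b-value diffusion-weighted MRI attenuates the water signal with
diffusion weighting `b` (s/mm²). The direction-averaged signal of a voxel is
modelled as a sum of three mono-exponential compartments,

$$S(b) = C_1 e^{-b\,\mathrm{ADC}_1} + C_2 e^{-b\,\mathrm{ADC}_2}
       + C_3 e^{-b\,\mathrm{ADC}_3},$$

with the compartment diffusivities fixed across voxels
($\mathrm{ADC}_1 < \mathrm{ADC}_2 < \mathrm{ADC}_3$, mm²/s): restricted
diffusion (tumor cells, fatty tissue), hindered diffusion (tumor and
fibroglandular tissue), and free/vascular water. Fixing the diffusivities
makes the voxel-wise fit *linear* in the unitless contributions
$C_i \ge 0$.

Two consequences drive the implementation:

* **Exact non-negative least squares.** With three unknowns, the NNLS
  optimum is the best-residual solution among the $2^3$ support sets whose
  unconstrained sub-fit is feasible; `fit_components()` enumerates them with
  one shared design matrix for all voxels, so the fit is exact (no iterative
  solver, no tolerance knob) and fully vectorized. Non-negativity is on by
  default because the $C_i$ are physical signal fractions and unconstrained
  fits go negative under noise; `nonneg = FALSE` restores the plain linear
  fit.
* **The diffusivity triple is configuration, not a constant.** Published
  values are protocol-specific; the package ships
  `example_fixed_adcs()` = (1.0e-4, 1.5e-3, 1.0e-2) mm²/s as a documented
  example spanning the three regimes, used by the phantom and the tests. An
  analysis of real data must supply the triple calibrated for its
  acquisition.

Per patient, maps are normalized to the 95th percentile of
$\sqrt{C_1 C_2}$ inside the healthy contralateral control ROI
(`normalization_factor()`), computed with the sorted-order linear
interpolation convention at rank $(n-1)\,0.95$ (`stats::quantile` type 7) —
recorded explicitly because percentile conventions differ across software.
All three components are divided by the factor (the classifier only
consumes $C_1, C_2$, but keeping $C_3$ on the same scale costs nothing).
Normalizing the *fitted maps* rather than the raw signal is equivalent for
a linear fit and keeps the fit itself scale-free; the test suite asserts
end-to-end invariance of the normalized maps under global signal scaling.

## The pooled posterior classifier

Normalized $(C_1, C_2)$ pairs from every patient's pre-treatment cancer and
control ROIs are pooled and binned on a shared 2D grid (default 128 × 128
bins spanning $[0, q]$ per axis, $q$ the pooled 99.5th percentile — the tail
is clamped into the edge bins, as are out-of-range values at lookup time:
extreme contributions beyond the training range are more plausibly
edge-class than undefined). Each class histogram is smoothed with a small
Gaussian kernel (default 1 bin; edge-renormalized), floored with a
pseudocount, normalized to a probability mass function, and converted to a
posterior probability of cancer

$$P(\text{cancer} \mid C_1, C_2)
  = \frac{f_{ca}\,\pi}{f_{ca}\,\pi + f_{co}\,(1-\pi)},$$

with prior $\pi = 0.5$ by default, which makes the posterior a pure density
ratio; both $\pi$ and the binning are configurable.

One numerical choice deserves emphasis. The pseudocount is expressed as a
*fraction of each class's training mass* spread uniformly over the grid
(default 0.5), not as a flat per-bin count. Control ROIs are typically an
order of magnitude larger than cancer ROIs; a flat pseudocount would hand
the smaller class a higher floor density after per-class normalization, so
every bin never seen in training would lean toward *cancer* (posterior
$\approx N_{co}/(N_{ca}+N_{co})$), and noise-scattered background voxels
would classify positive and flood the search region. With the class-scaled
form, unseen bins sit exactly at the prior, and the strict `> 0.5`
classification threshold excludes them.

Training pools all patients at the pre-treatment timepoint (the classifier
is global and is never retrained at later timepoints); per-patient tables
can be built by passing a single study to the training command.

## Automatic sizing geometry

All geometry works in physical millimetres on anisotropic voxel grids under
one convention: voxel index $(i,j,k)$ (0-based) sits at
$\mathrm{origin} + (i s_x, j s_y, k s_z)$, and distances are between voxel
centres.

1. **Tumor-containing region.** The pre-treatment cancer ROI is dilated by
   10 mm (`expand_roi()`): the output contains exactly the voxels whose
   centre lies within the distance of some ROI-voxel centre (exact
   Euclidean offset enumeration, respecting anisotropic spacing).
2. **Connected growth.** Any connected component of the classified mask
   that intersects the region is absorbed whole
   (`attach_connected_growth()`), so tumor growth spilling out of the
   dilated region is not truncated. "Connected to the region" is read as
   voxel-set intersection; a face-adjacency reading is available via
   `attachment = "adjacent"`.
3. **Largest component.** The maximum-cardinality connected component of
   (classified ∧ region) is extracted. Connectivity defaults to the full
   26-neighbourhood (6/18 configurable) — the most inclusive standard
   choice, appropriate for 2.5 × 2.5 × 5 mm voxels where diagonal contact
   is anatomically contiguous. Size ties are broken toward the component
   containing the smallest linear voxel index, for determinism.
4. **Longest diameter.** The maximum pairwise centre distance in mm,
   divided by 10. Since any 3D chord lies in *some* plane, the full 3D
   maximum realizes "longest diameter in any plane"; a slice-restricted
   axial mode (`plane = "axial"`) is provided for protocols that measure
   in-plane only. Empty and singleton components measure 0 cm — the centre
   convention's natural floor, matching the 0 cm reported for complete
   radiological responses. For large components the search is restricted
   to boundary voxels first (extreme points lie on the boundary), keeping
   the all-pairs step quadratic only in the surface.

The single pre-treatment ROI is reused at every timepoint (volumes are
assumed co-registered; registration itself is out of scope), so manual
input is needed exactly once per patient.

## ADC comparator

The conventional apparent diffusion coefficient uses only the b-values
below 1000 s/mm² of the same acquisition (0 and 500 in the reference
protocol): per voxel, minus the OLS slope of $\log S$ against $b$, which
reduces to the two-point log-ratio closed form. Voxels with any
non-positive retained signal are undefined; `mean_adc()` averages defined
voxels of the pre-treatment cancer ROI, additionally dropping exact-zero
ADC values. Negative estimates (possible under noise) are retained by
default — only zero and infinite values are excluded — with
`exclude_negative = TRUE` available.

## Endpoint statistics

Non-pCR (residual invasive disease at surgery) is the positive class
throughout: the clinically actionable call is identifying non-responders.
Directionality is explicit per modality — larger size ⇒ more likely
non-pCR; *lower* mean ADC (and smaller ADC increase) ⇒ more likely non-pCR,
encoding the a priori expectation that ADC rises with response.

* **AUC** is the Mann–Whitney probability with ties counted ½ (equals the
  trapezoidal ROC area); its CI is a Wald interval on the DeLong variance.
* **Operating points.** Candidate thresholds are midpoints between adjacent
  distinct scores plus the two degenerate rules. The headline point
  maximizes accuracy; ties prefer higher specificity, then fewer positive
  calls (the more conservative rule) — the data do not determine a unique
  threshold, so the tie-break is declared rather than silent. A second
  point maximizes sensitivity subject to specificity ≥ 0.90.
* **Proportion CIs** are exact Clopper–Pearson (beta quantiles): at n = 10
  to 27 per margin, asymptotic intervals are untrustworthy, and the exact
  form reproduces published intervals from their integer counts.
* **Paired tests**: exact binomial McNemar on the discordant pairs
  (chi-square variant behind a flag), applied separately within true
  positives (sensitivity) and true negatives (specificity); DeLong's
  structural-component test for correlated AUCs. Alpha is recorded as
  0.025, reflecting correction for two primary outcomes.
* **Relative change** $(x_t - x_{pre})/x_{pre}$ floors at −1 for vanishing
  lesions; Δ analyses include only patients imaged at all four timepoints.
* Displayed tables round half away from zero at 2 decimals (R's `round()`
  is half-to-even and would disagree with conventionally rounded published
  tables).

## The synthetic phantom

The phantom exists so that every pipeline stage is testable end-to-end
without patient data. It emulates: the acquisition geometry (64 × 64 × 16
voxels at 2.5 × 2.5 × 5 mm; b = 0/500/1500/4000 s/mm²), a two-breast
tissue layout (fat with a fibroglandular core per side, the contralateral
side providing the control ROI), an ellipsoidal tumor (default semi-axes
10 × 6 × 6 mm = 2.0 cm longest diameter, per-patient size variation 0.9–2.4×
with mild per-axis jitter, giving pre-treatment diameters of roughly
1.8–4.8 cm), a four-timepoint shrinkage schedule tied to the pCR label
(responders shrink progressively and vanish at post-treatment; non-pCR
patients shrink by at most 20 % in diameter), and Rician magnitude noise
(`sqrt((S+g_1)^2 + g_2^2)`; default σ = 0.09 ≈ SNR 20 at b = 0 in tumor —
a Gaussian mode exists behind a flag). Tissue component triples
(fat (0.7, 0.1, 0.1), fibroglandular (0.1, 0.6, 0.2), tumor
(0.9, 0.8, 0.1)) encode the qualitative structure — fat C1-dominant,
fibroglandular C2-dominant, tumor elevated in both — with no claim of
matching any population's fitted values. Per-patient seeds derive
deterministically from one master seed, so cohorts are reproducible and
patients independent of generation order.

What it does **not** emulate — and what passing tests therefore cannot
show: realistic anatomy and partial-volume mixtures, registration error
between timepoints, eddy-current/motion/distortion artifacts, coil
inhomogeneity, necrotic cores, or overlap between tumor and healthy
component distributions as severe as real tissue can exhibit. Pipeline
recovery on the phantom validates the machinery, not clinical performance.

## Problem sizes and runtime choices

The test suite runs unit oracles on small grids (≈ 10³–10⁴ voxels) and two
cohort-scale checks on the full 64 × 64 × 16 grid: a noiseless 27-patient
cohort (10 pCR with full shrinkage, 17 non-pCR with ≤ 20 % shrinkage) that
must yield sensitivity = specificity = 1 at the 0.75 cm post-treatment
threshold with pre-treatment diameters within one voxel diagonal
(0.61 cm) of the configured major axes, and oracle checks for AUC (200
random tied instances) and the DeLong test (20,000-replicate bootstrap
difference test, agreement within 0.05). The acceptance script repeats the
cohort run noiselessly and at SNR ≈ 20. The full suite completes in well
under a minute on one CPU.

## Known limitations

* The diffusivity triple and tissue contrasts are not estimated from data;
  misspecified `ADC_i` bias the $C_i$ and hence the classifier.
* The histogram classifier needs pooled training voxels at the few-thousand
  scale; very small cohorts produce grainy posteriors (the pseudocount then
  dominates and the map shrinks toward the prior).
* Diameters are quantized by the voxel lattice: sub-voxel size changes are
  invisible, and any measured diameter carries up to about one voxel
  diagonal of discretization error.
* `evaluate_cohort()` requires both classes present in every analyzed
  block; degenerate single-class cohorts are rejected rather than scored.
* DeLong p-values rely on asymptotic normality; at n ≈ 17–27 they are
  indicative, which is why the exact McNemar test accompanies them.
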