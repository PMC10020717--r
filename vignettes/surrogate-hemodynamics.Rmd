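---
title: "Centerline-based surrogate modelling of aortic valve hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-based surrogate modelling of aortic valve hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(centerflow)
```

## The problem

Aortic stenosis (AS) narrows the aortic valve orifice and obstructs
left-ventricular outflow. The clinical severity measure is the
transvalvular pressure gradient (TPG): inlet pressure minus the pressure at
the point of highest recovery downstream of the valve. Patient-specific
computational fluid dynamics (CFD) can compute TPG and wall-shear-stress
(WSS) from imaging, but takes hours per case. A trained sequence model can
produce the same centerline-resolved quantities in milliseconds.

`centerflow` implements that surrogate pipeline end to end at desk scale:
a parametric generator of synthetic aorta+valve geometries, a reduced-order
quasi-1D physics model standing in for CFD, the compact centerline-based
representation, a shape autoencoder, a bi-directional LSTM surrogate, and
an evaluation layer (RMSE/NRMSE, TOST equivalence of TPG, cohort
statistics, perturbation explainability).

## The compact representation

All quantities live on a discrete centerline with 2 mm point spacing
(typically 110–130 points for a 220–258 mm aorta). Static pressure is
averaged per centerline-orthogonal cross-section; in the valve region only
the leaflet-bounded orifice area contributes. WSS is averaged over the
vessel-wall segment between adjacent cross-sections and assigned to the
upstream point; the last point repeats the last segment so input and
output sequences share length N. Cross-section orientation follows a
rotation-minimizing frame: the method never needs an absolute in-plane
orientation, and a twist-free frame prevents spurious rotation of the
rasterized shapes along the arch, which would corrupt the autoencoder
codes.

Two open choices were resolved as follows. Pressure averaging is the plain
sample mean (not area-weighted): the sampled points are area-uniform by
construction, so the two coincide in expectation, and the sample mean is
what the field sampler can reproduce exactly at zero noise. Rasterization
uses a fixed 50 mm physical window rather than per-section normalization,
so absolute size survives in the shape image; scale is informative over
and above the separate area feature.

## Synthetic geometries

Each case is a candy-cane centerline (straight LVOT/valve/ascending limb,
~180 degree arch, descending limb) with a mild seeded out-of-plane bow of
the arch (2–5 mm), smooth diameter jitter (up to about 4% in area) and
mild ellipticity (axis parameter up to 0.12). Segment length fractions are
fixed at LVOT 10%, valve 5%, ascending 30%, arch 25%, descending 30%.
Cross-section area interpolates monotone-cubically between segment
diameters and dips to the valve orifice area exactly at the valve
midpoint; the valve boundary is an n-leaflet "tri-star" polygon scaled to
the target area, emulating a fully open tricuspid orifice.

Default sampling ranges are literature-plausible rather than
cohort-matched (the source imaging cohort reports no aortic diameters or
lengths): LVOT diameter 20–26 mm, ascending 26–34 mm, descending 20–26 mm,
total length 220–258 mm. The upper length bound is set so that 2 mm
resampling always yields at most 130 points, keeping every synthetic case
inside the 110–130 point regime the sequence model is designed around.
Two AVA regimes are provided: the default preset samples AVA uniformly on
0.4–2.0 cm^2 (healthy through severe), and an AS-cohort preset draws from
a truncated normal (0.74 ± 0.17 cm^2 on 0.4–1.1) emulating a
TAVI-referral population.

## The reduced-order oracle

The physics stand-in is a quasi-1D extended-Bernoulli march with
irreversible losses, in SI units internally (1 mmHg = 133.322 Pa), blood
density 1050 kg/m^3 and constant (infinite-shear) viscosity 0.0035 Pa s:

- mean velocity per point `v_i = Q / A_i`; in the valve region the
  effective jet area is `cc * A_i` with contraction coefficient
  `cc = 0.85`, so the minimum pressure sits at the vena contracta;
- Darcy friction with `f = 64/Re` below Re 2300 and the Blasius
  correlation `0.316 Re^-0.25` above, accumulated trapezoidally;
- a Borda–Carnot expansion loss `K * 0.5 rho (V_vc - V_ds)^2` (K = 1)
  downstream of the vena contracta. The loss fraction applied at a point
  is the maximum of a linear ramp over the recovery length (40 mm) and
  the locally expansion-matched fraction
  `(V_vc^2 - v_i^2) / (V_vc^2 - V_ds^2)`. The second term guarantees that
  the marched pressure can never recover above the inlet while the lumen
  re-expands (TPG stays non-negative for any admissible geometry); the
  first term spreads the residual jet-mixing loss over the recovery
  length, producing the characteristic partial pressure recovery in the
  ascending aorta.
- WSS combines the Darcy wall estimate `(f/8) rho v_i^2` with a
  jet-impingement term `0.02 * 0.5 rho V_vc^2 * exp(-(s - s_vc)/40mm)`
  downstream of the vena contracta, which places the WSS peak inside the
  valve region and produces elevated, slowly decaying WSS in the
  ascending aorta.

Pressures are finally shifted so the outlet reads 130 mmHg, mirroring the
post-processing convention for presentability; all pairwise differences
(hence MPD and TPG) are unaffected. The oracle's WSS magnitudes are
plausibility-tuned synthetic values — no quantitative WSS-geometry
relationship was available to match — and run high (hundreds of Pa) for
severe orifices at the default jet gain.

The field sampler emulates the within-plane variability of 3D CFD fields:
per-section pressure samples spread by 5% of the local dynamic pressure
and per-segment WSS samples with a von-Mises-shaped circumferential
asymmetry downstream of the valve (jet impingement), whose circumferential
mean is exactly the profile value. At zero noise the averaging pipeline
reproduces the oracle profile bit-exactly, which pins down the averaging
semantics independently of Monte-Carlo tolerances.

## Dataset assembly

Modelled peak-systolic flow rates are drawn from a truncated normal whose
mean shifts with orifice area, `mu_Q = 150 + 250 * AVA` ml/s (SD 15%,
truncated to 100–700 ml/s) under the default preset. The AS-cohort preset
uses `mu_Q = 110 + 140 * AVA` (SD 18%): with the orifice relation
`MPD ~ rho/2 (Q / (cc AVA))^2`, these values put the cohort's maximum
pressure drops in the clinically reported span (~0–120 mmHg, median near
40), which the steeper default model would overshoot for small orifices.
Each baseline case gains ±25% flow variants (re-solved, not rescaled), the
MPD filter removes cases above 120 mmHg (boundary inclusive — cases are
excluded for drops *in excess* of the bound), and geometries are dealt
round-robin by sorted baseline MPD into 11 subsets (1 test + 10
cross-validation folds) with seeded tie-shuffling. Round-robin dealing is
the simplest scheme that makes every subset span the retained MPD range;
all flow variants of a geometry stay in one subset, so test geometries are
never seen in any form during training.

Coordinates are pose-normalized (inlet at origin, initial tangent along
+z, centroid azimuth zeroed) because synthetic cases would otherwise share
a trivially identical pose; features are per-column z-scored with
statistics fitted on training subsets only.

## The sequence model

The shape autoencoder is a classic single-hidden-layer network: 68 x 68
binary raster flattened row-major, logistic-sigmoid encoder to m = 4
codes, sigmoid decoder, mean-squared reconstruction loss, full-batch Adam
(learning rate 0.01, 1200 epochs). No sparsity regularization is applied
by default. It is trained on vessel and valve sections pooled across
training geometries, because the LSTM consumes codes at every point.

The surrogate is a bi-directional LSTM over the per-point feature rows
`[x, y, z, area, Q/A, code_1..code_4]` (width 9), followed by a tanh
fully connected layer and a linear two-channel head (pressure, WSS, in
z-scored units). Desk defaults are 64 hidden units per direction and a
32-unit head, trained with Adam (learning rate 2e-3, batch 64, gradient
norm clipped at 1, 60 epochs); the published-scale sizes (hidden 900,
head 200) are reachable through the same configuration object but take
hours under cross-validation, so the desk sizes are what the test
benchmarks use. The loss is plain MSE with equal weight on both
standardized channels. Variable sequence lengths (110–130) are handled by
right-padding with masked loss; the backward direction runs on
per-sequence-reversed input so padding stays behind the valid samples in
both directions and never contaminates states. The LSTM backward pass is
verified against finite differences in the test suite.

## Evaluation

Per-case accuracy uses RMSE and normalized RMSE: pressure residuals are
divided by the case's reference maximum pressure drop (inlet minus
infimum) inside the sum — algebraically equal to RMSE/MPD, and tested for
that equality — and WSS residuals by the reference WSS supremum.

TPG equivalence between surrogate and reference uses the two one-sided
tests (TOST) procedure on paired differences with margin ±5 mmHg (the
accuracy of catheter-based pressure measurement) at alpha 0.05 (the
conventional level; the source analysis reports only p < 0.001). Both
one-sided hypotheses are tested with Wilcoxon signed-rank tests because
TPG is not normally distributed. The signed-rank null is computed exactly
for n <= 25 by dynamic programming over the signed ranks — this stays
exact under ties and under Pratt's treatment of zero differences, which
`stats::wilcox.test` cannot do — and by a tie-corrected normal
approximation above. Cohort summaries use linear-interpolation quantiles
(type 7) for medians/IQRs, Pearson correlations of absolute RMSE against
MPD and peak WSS, a Wilcoxon rank-sum comparison of test-subset versus
cohort MPD, and a Lilliefors normality test whose critical values come
from a seeded 10^4-replicate parametric bootstrap.

Explainability follows the local perturbation recipe: one feature is
shifted by ±1 training SD over a 7-point window (half-width 3, i.e. ±6 mm
— "locally" is otherwise unspecified) and the output RMSE against the
unperturbed prediction is averaged over the two signs.

## Benchmarks, problem sizes and what they show

The package's own benchmark trains the desk-default surrogate on 100
synthetic geometries x 3 flow conditions (MPD-filtered, 11-subset split,
test subset held out) and evaluates the held-out subset; the autoencoder
quality benchmark uses a 220-shape corpus with a 40-shape hold-out. These
sizes keep the full suite in the tens of minutes on one CPU while leaving
the learning problem non-trivial. On this benchmark the held-out median
pressure and WSS NRMSE land well under 10% and the TOST declares TPG
equivalence at ±5 mmHg, with valve-region perturbations dominating
descending-aorta perturbations — the qualitative behaviour expected of a
faithful implementation.

What passing these benchmarks does *not* show: accuracy on real patients.
The synthetic generator varies size, orifice area, arch curvature and
flow, but real cohorts add segmentation noise, non-circular dilated roots,
branching-vessel effects, turbulent 3D recovery structure and imaging
artifacts, none of which are emulated. The oracle is a smooth quasi-1D
model: it is a far easier regression target than 3D CFD fields, so
synthetic NRMSE values are not comparable to clinical ones.

## Numerical choices and degenerate inputs

- Exact-area polygons: boundary polygons are scaled so the shoelace area
  matches the target exactly; the valve minimum is snapped onto the 2 mm
  sampling grid so the minimum valve-region section area equals AVA.
- Geometries whose arch curvature radius does not exceed the lumen radius
  are rejected as self-intersecting.
- Zero-variance feature columns (possible in degenerate configurations)
  are left unscaled with a warning, and their perturbation sensitivity is
  zero by definition.
- A profile whose pressure minimum is the last point has no downstream
  recovery segment; TPG falls back to inlet minus outlet with a warning.
- Ties in grid search break toward the smaller model, then config order.
- All randomness flows from one master seed through a documented
  stage-hash derivation, so any stage can be reproduced in isolation and
  two runs with the same config are bitwise identical.

A caveat on the code space: at the default (reconstruction-optimal)
learning rate the four sigmoid code units tend to saturate, collapsing
the code toward a single effective axis dominated by cross-section area;
shapes from different families with similar areas then receive similar
codes. A gentler rate keeps all units active at a small reconstruction
cost. Independently, the binary raster aliases sub-pixel boundary changes
into a few arbitrary pixel flips, so code-space locality is only
meaningful for shapes separated by at least a few percent in area. Both
effects are visible in the code-space continuity test, which probes the
property at that resolution.

## Known limitations

- The oracle has no turbulence, secondary flow or unsteadiness; WSS
  fluctuation in the ascending aorta is represented only by a smooth
  decaying jet term.
- The generator produces tricuspid-like star orifices only; bicuspid and
  prosthetic valve shapes are out of scope.
- User-supplied surface meshes must come with a centerline; no
  skeletonization is implemented.
- The AS-cohort flow model is a two-parameter calibration to a published
  MPD distribution, not a physiological flow model.
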