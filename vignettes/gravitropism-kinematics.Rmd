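---
title: "Quantifying gravitropic bending: models, fields, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gravitropic bending: models, fields, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravikine)
```

## The model and its assumptions

A dark-grown hypocotyl turned to the horizontal bends back toward the
vertical. We describe the organ at each frame by its median: a planar curve
parameterized by arc length $s$ from the base ($s = 0$) to the tip, with
local deflection angle $A(s,t)$ measured from the upward vertical (0° =
vertical, 90° = the initial horizontal posture, negative = overshoot past
vertical) and local curvature $C = \partial A / \partial s$ in mm⁻¹. Two
bending laws are compared:

* sine law: $\partial C/\partial t = -\beta \sin A$;
* graviproprioception (GP): $\partial C/\partial t = -\beta \sin A - \gamma C$,
  with $\beta > 0$ the gravitropic gain (mm⁻¹ h⁻¹) and $\gamma > 0$ a
  proprioceptive decay (h⁻¹) by which the organ straightens regions it
  senses as curved. The sine law is the nested case $\gamma = 0$.

Assumptions baked into the analysis: the organ is effectively planar in the
imaging plane; the base is clamped at a fixed angle; elongation is slow
enough that fields at fixed $s$ are meaningful (the simulator offers a
uniform-growth switch to stress-test this, default off, because the
analysis uses partial, not material, derivatives); and the luminescence
gradient across the organ is well summarized by the ratio of two points at
1/8 of the diameter inside each flank.

## The synthetic scene

No public raw recordings exist for this kind of experiment, so validation
rests on a forward simulator with rendered frames and retained ground
truth.

* **Dynamics.** `simulate_gp_rod()` integrates the GP law by explicit Euler
  steps (default `dt_inner` = 0.005 h) on a fixed arc grid (`ds` = 0.02 mm),
  recomputing $A = A(0) + \int_0^s C\,ds'$ every step. Explicit Euler was
  chosen for auditability; the dynamics are smooth and slow, halving the
  step changes $C$ by well under 0.5 %, and an independent RK4 integration
  agrees to better than 1 % (both are tested).
* **Study conditions.** Frames every 0.170 h over 6.10 h; rod length 4 mm,
  diameter 0.25 mm, base angle 90°; β = 0.4 mm⁻¹ h⁻¹, γ = 1.5 h⁻¹ for the
  reference scene.
* **Initial curvature.** The reference validation scene uses a gentle
  spatial perturbation $C(s,0) = 0.25 \sin(2\pi s/2.2 + 0.7)$ mm⁻¹ rather
  than a perfectly straight rod. This is both realistic (seedlings are
  never perfectly straight) and statistically necessary: starting from
  uniform $C = 0$, the fields $\sin A(s,t)$ and $C(s,t)$ evolve almost
  proportionally along $s$ at every $t$, so the per-timepoint regression
  that separates β from γ is ill-conditioned no matter how good the
  measurements are. A spatially structured initial curvature decouples the
  two regressors (design condition numbers drop from several hundred to
  ~10–30 in the transient) and makes parameter recovery a meaningful test.
* **Rendering.** 512×512 rasters at 16 µm/pixel (the pixel scale is a
  declared default, not an inferred one). The bright channel is the rod
  silhouette with a flat cut at the clamped base and a rounded
  (hemispherical) tip, anti-aliased over one pixel. The luminescence
  channel carries a longitudinal profile (counts) with a log-linear
  transverse gradient pinned so that the log10 ratio between the two
  1/8-inset points equals the ground-truth LRL exactly; the ground truth is
  pinned at those points because that is where LRL is defined. The default
  LRL truth is $-\kappa \sin A(s, t-\tau)$ with κ = 0.5 and τ = 1.5 h,
  reflecting the observed lag between turning and the first
  differential-expression signal; before the turn the organ is vertical, so
  the pre-delay LRL is 0. Noise is Poisson counting noise plus Gaussian
  read noise (sd 2 counts) with explicit seeds.
* **What the scene does not emulate.** No optics (PSF, vignetting, EM
  gain), no cotyledons or apical hook, no organ growth by default, and the
  LRL ground truth is a smooth designed function rather than real promoter
  dynamics. Passing tests therefore demonstrate that the *analysis chain*
  is accurate and unbiased on organs that obey the stated laws — not that
  real seedlings obey them.

## Midline extraction

Per frame: Otsu thresholding, largest connected component, hole filling;
the outline is split into two flank polylines at the two points of maximal
geodesic (within-mask) separation, found by a double BFS sweep on the pixel
lattice — this is robust for strongly bent, partially hooked shapes where
Euclidean extremes fail. Each flank vertex is paired with its nearest point
on the other flank; midpoints and local widths form the cloud through which
a principal curve is fitted (Hastie–Stuetzle: initialize on the first
principal component, then alternate projection and coordinate-wise cubic
smoothing-spline fits at equivalent df = 10, where df is the trace of the
smoother matrix — the standard R convention). The fitted median is
resampled every 19.9 µm from the base.

Numerical details worth knowing:

* Midpoints whose flank separation is far from the median width, or which
  sit within ¾ width of an extremity, are discarded: around the tip cap and
  the clamp edge, nearest-point pairing is meaningless. The discarded end
  regions are then reinstated geometrically — the median is extended along
  its end-fitted arc to the silhouette boundary (minus half the local width
  at the rounded tip), so that $s = 0$ sits at the base edge and the total
  length matches the organ. Extending along the local arc rather than the
  tangent avoids planting a curvature kink at the junction.
* Traced contours run through boundary-pixel centres, about half a pixel
  inside the physical surface on each flank. Widths are therefore corrected
  by one pixel, and inset contours reduce their inward offset by half a
  pixel (`surface_offset`). Without these corrections the LRL magnitude is
  systematically underestimated by ~10 %.
* The base is identified as the extremity nearer the raster border on the
  first frame, and as the extremity nearer the previous frame's base
  afterwards, keeping orientation stable across a series.
* On noiseless rendered scenes the extracted median lies within ~0.1 pixel
  (perpendicular) of the truth; the residual error budget of the curvature
  field is dominated by the df-10 principal curve's small-scale flexure
  (~0.1° in angle), not by localization.

## Fields and trough analysis

$A(s)$ comes from centred-difference tangents of the resampled median,
unwrapped along $s$; angles are radians internally, degrees at every
interface. $C(s)$ is the first derivative of a cubic smoothing spline of
$A$ vs $s$ at equivalent df = $n/2$ (the half-the-data-size rule used for
all profile smoothing in the package). Per arc position, a spline of $C$
against $t$ (df = $n/2$, at least 8 valid frames) yields the predicted $C$,
its derivative $\partial C/\partial t$, and SEE = √(RSS/(n − df)) with the
spline's equivalent df — the standard smoothing-spline residual convention.
The SEE is computed once per $s$ over the full time series (the simplest
reading of a global residual), and the $t$–$s$ SEE-ratio map
$\log_{10}(\mathrm{SEE}/|C|)$ varies through $|C(s,t)|$ only; it flags the
early (< ¾ h) and basal (< 0.5 mm) region where rate estimates are
unreliable.

Troughs (and heights) of a field are detected algorithmically — per arc
position, local extrema over time deeper than half the global extreme, then
linked across neighbouring arc rows by nearest-time continuity (gaps up to
two rows, deeper extremum wins ties) and kept if they span ≥ 0.5 mm.
Alignment with the angle field reads $A$ at each path vertex (bilinear) and
snaps the median to the nearest 5°, reporting the RMS residual. On scenes
whose response kernel is designed to peak at a known angle $A^\*$, this
procedure recovers $A^\*$ within one 5° step in ≥ 95 % of noise replicates.

## Luminescence profiles

The convex/concave labels are fixed per recording from the sign of the
$|C|$-weighted mean curvature (a never-bending recording is an error unless
a fallback orientation is configured). Inset contours are fitted at df = 60
through flank points moved inward by 1/8 of the local diameter (the local
flank separation at the nearest median point, not a global mean). At each
median point the normal line is intersected with both inset curves (nearest
intersection within twice the local width, otherwise that arc position is
masked rather than extrapolated); intensities are sampled bilinearly —
sub-pixel points make per-pixel readout inappropriate — and normalized by
exposure (synthetic frames carry 1 min). Profiles are smoothed along $s$ at
df = $n/2$ and LRL is recomputed from the smoothed $L_c$, $L_v$. LRL is
exactly antisymmetric under label swap and invariant to global intensity
scaling; on the reference noisy scene the LRL map matches its ground truth
with RMS ≈ 0.03.

## Model fitting and selection

Per timepoint, `fit_gp()` regresses the response on $-\sin A$ and $-C$
without an intercept (the bending law has none; an intercept is available
as an option since published analyses do not always state the choice).
Standard errors and p-values come from the t-distribution; coefficients
with p > 0.05 are flagged insignificant. AIC uses the Gaussian likelihood
with the variance profiled out and k = coefficients + 1, identically for
both models, so only differences matter. Without an intercept the adjusted
R² uses the uncentered total sum of squares and is not comparable to
centered values — it is reported for within-comparison only. Collinearity
(condition number > 1e8) flags the fit rather than failing it.

Two windows matter in practice and are exposed as `s_min`/`s_max` rather
than hard-coded: a basal cutoff (the clamp region, mirroring published
apical restrictions) and an apical cutoff (the last ~0.8 mm, where
end-of-spline curvature estimates are noisiest). Identification of β and γ
is only well-posed in the transient (here roughly $t \lesssim 1/\gamma$
after response onset): at quasi-steady state $C \to -(\beta/\gamma)\sin A$
and the regressors become collinear again. The validation therefore
evaluates recovery over the transient window (0.3–1.6 h) with s in
(0.5, 3.2) mm; medians recover β and γ within ~10 % through the full image
pipeline, and AIC prefers the GP model at every timepoint there. With
γ = 0 data, AIC prefers the sine law in the majority of replicates, as the
2-unit parameter penalty dictates for a nested pair.

The sine-law segment scan regresses LRL on $\sin A$ over every contiguous
window ≥ 0.76 mm and retains windows with R² > 0.95, merging them into
maximal segments colored by the sine-law gain β. Here R² is the squared
correlation (centered), not the uncentered no-intercept statistic: an
angle-independent (constant) LRL has near-unit uncentered R² against the
slowly varying $\sin A$ and would be retained everywhere, which
contradicts the scan's purpose of localizing where LRL *follows* the sine
law. The reported β is still the no-intercept-consistent slope of LRL on
$-\sin A$.

## Problem sizes used in validation

The shipped tests and the acceptance script run the reference scene at its
native size (36 frames of 512×512 pixels, ~200 arc points), one full
image-analysis pass, and 50-replicate loops for the stochastic claims
(noise-perturbed ground-truth fields rather than 50 re-rendered image
series — re-rendering only adds midline localization error, which the
single full pass already quantifies). A complete test run takes on the
order of a minute.

## Known limitations

* Curvature and rate estimates within ~0.5 mm of the base and ~0.8 mm of
  the tip are markedly noisier; the SEE-ratio map makes this visible and
  the fitting windows exclude it.
* The df = $n$/2 smoothing rule is kept for fidelity to established
  practice; it under-smooths the angle profile for derivative estimation,
  and the curvature field inherits ~4–5 % RMS error (relative to the field
  maximum) at 16 µm/pixel.
* Trough detection is parameterized (depth fraction, linking window) where
  published figures may have been traced by hand; defaults were chosen on
  the simulator and are configurable.
* The per-timepoint regression treats arc samples as independent; spatial
  autocorrelation from smoothing means the reported standard errors are
  optimistic. Model *selection* (AIC differences) is unaffected in the
  nested comparison.
* No material-derivative analysis and no special handling of the apical
  hook.
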