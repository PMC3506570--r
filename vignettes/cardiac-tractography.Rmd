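---
title: "Quantitative cardiac DT tractography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cardiac DT tractography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotract)
```

## The measurement model

Water in myocardium diffuses preferentially along myofibers, so the
principal eigenvector $\hat e_1$ of the per-voxel diffusion tensor $D$ is
taken as the local fiber direction. `fit_tensor()` estimates $D$ from
diffusion-weighted signals by unweighted log-linear least squares on
$\ln(S_i/S_0) = -b_i\, g_i^\top D\, g_i$; multiple $b=0$ volumes are
averaged before the log transform. Weighted or positivity-constrained
fitting is deliberately not offered: the fit is exact on noiseless data,
deterministic, and adequate at the noise levels the phantom emulates.
Voxels with non-positive signal are flagged and excluded (their tensors
are `NA` and tracking treats them as impassable) rather than clamped,
because clamping eigenvalues would silently distort the helix angles
derived from them.

## Helix angle and the LV frame

At a wall point, the local orthonormal triad is circumferential $\hat c$,
longitudinal $\hat l$ (the LV long axis) and outward radial $\hat r$, with
$\hat c = \hat l \times \hat r$. The helix angle of a fiber $f$ is

$$\mathrm{HA}(f) = \operatorname{atan2}(f\cdot\hat l,\ f\cdot\hat c)$$

after flipping $f$ so that $f\cdot\hat c \ge 0$: fibers are axial
(orientations, not directions), so $\mathrm{HA}(f)=\mathrm{HA}(-f)$ and
the result lies in $(-90^\circ, 90^\circ]$. Fibers within $10^{-9}$ of the
radial direction have no defined HA; such vertices are excluded from tract
statistics and counted, never imputed. The only genuinely
convention-dependent choice — which helical handedness is "positive" — is
isolated in one constant (`ha_sign_convention()`); the package convention
makes subendocardial right-handed helices positive, with the long axis
pointing base to apex.

`fit_lv_frame()` recovers the frame from a myocardium mask. Because an LV
short-axis section is nearly circularly symmetric, the long axis is the
principal-component direction whose eigenvalue is most *isolated* from the
other two — the largest eigenvalue for an elongated ventricle, the
smallest for a short thick annulus. The center line is the per-slice mask
centroid, interpolated linearly between slices when the triad is
evaluated.

## Tracking

Streamlines grow bidirectionally from each seed by classical fourth-order
Runge–Kutta integration with a fixed step of one-fourth of the voxel size
(`step_fraction = 0.25`). At every RK4 stage the direction is the
component-wise trilinear interpolation of $\hat e_1$, after aligning each
contributing voxel's vector with the incoming direction
($\mathrm{dot} \ge 0$) and renormalizing — the cheapest deterministic
resolution of the eigenvector's antipodal ambiguity. Voxels outside the
mask get zero interpolation weight (with weight renormalization); if the
total in-mask weight falls below one half the branch terminates as a mask
exit. The backward branch integrates $-\hat e_1$ and the two branches are
concatenated through the seed, whose initial orientation is fixed
deterministically (first nonzero component positive); tract geometry is
therefore invariant under a global sign flip of the field.

A propagation angle above `max_propagation_angle = 35`° between
*consecutive step segments* (not per RK4 stage) is the single intrinsic
termination criterion. One consequence of smooth interpolation deserves
emphasis: a planar 40° direction discontinuity in the voxel field is
blended over roughly one voxel, so at quarter-voxel steps each individual
segment turns by only ~10° and tracking passes through. The criterion
binds on the *per-step* turn — sharper interfaces (for example 80°) or
larger steps do terminate exactly at the plane. The test suite asserts
both behaviors explicitly.

Two numerical details differ between the compiled tracker and the exported
reference integrator `rk4_streamline()`. The tracker renormalizes the
combined RK4 direction so consecutive vertices are exactly one step apart
(an invariant downstream code relies on); the reference integrator applies
the textbook update unmodified, because that is what carries the provable
$O(h^4)$ global error used in the convergence tests (~15× error reduction
per step halving on the analytic circular field; the tracker itself is
validated against the same field for radial drift $< 10^{-3}R$ per
revolution).

Length policies: `pi_r` caps each branch at $\pi R/2$ from the seed, so
the *total* tract length is at most half the LV circumference $\pi R$;
`roi_clip` stops growth when a point leaves the ROI; both are backstopped
by a hard cap of $10\pi R$ steps so no streamline is infinite. The
effective radius $R$ is the mean distance from the long axis over mid-wall
voxels (central third of transmural depth) in the central third of the
mask's axial extent, falling back to the whole mask for degenerate axial
bands.

## Whole-tract classification and regional curves

Each tract's discrete HA sequence (vertex tangent directions, adjacent
segments averaged) is reduced to its minimum, median, maximum and mean;
the median of an even count is the mean of the two central values. Tracts
whose discrete HA jumps by more than 90° between vertices are flagged
rather than unwrapped — at $(-90,90]$ with axial folding, such jumps
indicate wrap-around, and silent unwrapping would fabricate smoothness.

Regional curves use a two-step averaging: every valid tract deposits its
(min, median, max) into **every** ROI voxel its polyline traverses — not
only its seed voxel — which makes the curves independent of seeding
density; per-voxel deposit means are then averaged along the base–apex
direction (one 2D transmural × anterior–posterior map per statistic) and
finally along the anterior–posterior direction. Local ROI axes come from
the frame at the ROI centroid (transmural = $\hat r$, base–apex =
$\hat l$, anterior–posterior = $\hat c$), and each voxel's normalized
depth is its center-line distance scaled by the wall limits of the
myocardium mask within the ROI's axial band. Whole-tract statistics are
computed from the *full* tract even when only part of it lies inside the
ROI; only the deposition is ROI-limited (a documented choice — the
plausible alternative of restricting statistics to in-ROI vertices is what
the `roi_clip` length policy provides).

## TCI, histogram, variance ratio, zero-crossing

$$\mathrm{TCI} = \frac{\int_{\mathrm{endo}}^{\mathrm{epi}} \mathrm{HA}_{med}(x)^2\,dx}
{\int (\mathrm{HA}_{max}-\mathrm{HA}_{med})^2\,dx + \int (\mathrm{HA}_{min}-\mathrm{HA}_{med})^2\,dx}$$

with trapezoidal integrals over the valid samples on normalized depth, so
the index is a pure ratio (degrees² cancel; the formula is implemented
exactly as written, with no additional normalization). The mean-HA
classification is computed but excluded from the TCI. A vanishing
denominator with nonzero numerator — min and max hugging the median
everywhere — returns `Inf` with a `perfect` flag; an all-zero 0/0 is an
error. The index is even in HA (sign-flip invariant) and strictly
decreases as symmetric spread is added around a fixed median; both
properties are asserted in the tests. Values above 0.1 indicate coherent
πR-length datasets; ROI-clipped tracts, being shorter, accumulate less
along-tract HA variation and score systematically higher.

The variance ratio is the $n-1$ sample variance of strictly negative
median-HA values over that of strictly positive ones; exact zeros are
excluded from both sides (the documented tie-break), and fewer than two
values on either side flags the ratio undefined. It is computed from raw
values, never from binned counts, so the 5° histogram bin width affects
display only. The zero-crossing of the median curve is linearly
interpolated between bracketing samples; multiple crossings are all
returned with a flag.

## The phantom: what it states and what it does not

The generator emulates the mid-ventricular lateral wall where the
quantification ROI sits — a thick-walled annular cylinder segment, not a
truncated ellipsoid, because the wall is locally cylindrical there. The
defaults are the stated world of the package's validation: inner/outer
radius 24/30 mm, height 48 mm, 1 mm isotropic voxels (a 64³-scale grid),
linear transmural HA profile between `alpha_endo` and `alpha_epi`,
eigenvalues $(1.0, 0.7, 0.5)\times 10^{-3}\,\mathrm{mm^2/s}$ (physiologic
anisotropy ordering; HA is insensitive to the values), and 5° of per-voxel
orientation noise. Presets encode the species profiles as JSON configs,
not code: `normal-human` ±60°, `normal-sheep` ±50°, and `remote-zone`
+60/−37.5° — the epicardial value anchored to the most-epicardial
histology level of remodeled hearts, with the endocardial value unchanged
since the subendocardium is where remodeling is weakest. The actual
in-vivo transmural profile shape is not firmly established; linear is the
default and the profile argument accepts any function of depth.

Two optional refinements stand in for real-heart features the geometry
omits: an axial taper of $|HA|$ toward base and apex (off by default), and
an elevated-noise subendocardial band ($x<0.15$) emulating papillary and
trabecular incoherence (off by default). The phantom does **not** model
whole-heart anatomy, the infarct core, strain, perfusion fixation
artifacts, or acquisition physics beyond the mono-exponential forward
model $S_i = S_0 e^{-b g_i^\top D g_i}$ with optional Gaussian or Rician
noise. A green phantom test therefore establishes the correctness of the
computational chain under known architecture — not the biological values
of real cohorts, which come from specimens this package cannot conjure.

One geometric subtlety: even a perfectly symmetric ±50° architecture gives
a slightly skewed raw voxel-count HA distribution (skewness ≈ 0.08),
because outer (negative-HA) shells of an annulus contain more voxels than
inner ones. With respect to the wall depth measure (inverse-radius voxel
weights) the distribution is symmetric to numerical precision, and the
tract-level variance ratio lands near — just below — unity (≈ 0.92–0.96
across seeds). This is a property of the stated cylindrical world, not a
bug, and the tests assert both forms.

## Degenerate inputs and numerical tolerances

Eigenvector triads are orthonormal to $10^{-8}$ and reconstruction to
$10^{-12}$ relative (base R's symmetric eigensolver; ties in degenerate
tensors break by its deterministic output, with no re-orientation).
Tensor-fit round trips on noiseless forward-simulated data hold to
$10^{-10}$. Walls thinner than two voxels refuse to generate (the
transmural profile would be unresolvable); ROIs spanning fewer than three
depth samples refuse to produce a TCI. Seeds outside the mask are skipped
and counted; tracts shorter than `min_points = 3` vertices are discarded
and counted.

## Histology module

The ridge detector follows the standard Gaussian-scale Hessian recipe:
smooth at `scale_sigma` (default 2 px), eigendecompose the Hessian
per pixel, keep pixels whose principal curvature magnitude exceeds the
threshold (default: half the image-wide SD of principal curvature — the
reference criterion is described only as "local extrema of the principal
intensity curvatures", so scale and threshold stay exposed) *and* whose
intensity is extremal along the principal-curvature direction. Both
polarities are kept, since fibers and interstitial spaces are both
informative. The mask is thinned to single-pixel width (Zhang–Suen,
idempotent by test), chained into 8-connected components, and short chains
dropped. A segment's angle is the principal axis of its pixel-coordinate
covariance — more robust for curved segments than the endpoint chord. The
section mean is a length-weighted circular mean on the half-circle
(angles doubled, vector-averaged, halved): axial statistics are mandatory
because +80° and −80° segments average to ±90°, not 0°. Whether the
reference analysis weighted by length is unstated; length-weighting is the
default and `weighted = FALSE` the switch. Microscopy angles are mapped to
the MR convention through the same global sign constant.

## Known limitations

- The annular phantom cannot probe apex/base HA flattening beyond its
  simple taper, nor fiber-crossing or sheet (E2/E3) structure — transverse
  and sheet angles are out of scope.
- The tracker's termination semantics are per-step, as discussed above;
  probabilistic tractography and FA/MD thresholds are deliberately absent.
- NIfTI support is minimal by design (axis-aligned grids, pixdim only);
  datasets with nontrivial qform/sform rotations must be resampled
  upstream.
- Cohort-level statistics across hearts (group tests, LV volumetry) are
  out of scope; the package quantifies one dataset at a time.
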