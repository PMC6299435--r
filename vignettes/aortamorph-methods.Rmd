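---
title: "Quantifying aortic wall micro-structure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic wall micro-structure: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Phase-contrast microCT of paraffin-embedded murine aortae resolves the layered
micro-structure of the vessel wall without staining or sectioning: in a
transverse slice the lumen and the surrounding paraffin are dark, the tunica
media appears as a band of bright concentric elastic lamellae separated by
darker interlamellar tissue, and the adventitia forms a dimmer outer rim.
Because the intima produces no phase contrast, the internal elastic lamina
(IEL) is the visible border between lumen and wall. `aortamorph` turns such a
stack into per-slice histological parameters — lumen diameter, media
thickness, compartment cross-sectional areas, the medial fraction occupied by
lamellae — an en-face map of the IEL surface scored for breaks, and
between-group statistics over cohorts of samples.

The pipeline is deliberately deterministic and parameter-light: a single
configuration object drives every stage, all randomness is seeded, and
re-running a configuration reproduces byte-identical output tables.

# Pipeline stages and their models

## Wall and lumen segmentation

Each slice is binarised with an automatic threshold, smoothed by morphological
closing then opening with a disk (default radius 3 px), reduced to its largest
bright 8-connected component, and hole-filled — except for the largest
enclosed hole, which is the lumen candidate. The lumen is then the background
region enclosed by the wall, found by flood fill from the wall centroid; a
lumen that reaches the image border signals an open wall and routes the slice
to the fallback path.

Two automatic thresholds are available. The default is isodata
(Ridler–Calvard, the ImageJ default): the threshold iterates to the midpoint
of the two class means, so the binarised boundary of an antialiased edge falls
at roughly 50% edge coverage — i.e. at the true subpixel boundary — even when
the bright class has a long tail (the lamellae). Otsu's between-class-variance
criterion is provided as an alternative (`threshold_method = "otsu"`); it
places boundaries measurably further into the edge ramp on this kind of
trimodal histogram, which is why it is not the default. Both are invariant to
affine intensity rescaling.

Boundary contours are represented in polar form about the lumen centroid:
`K` angular samples (default 360) of the radius function, traced at subpixel
precision from the mask and then refined to the local half-maximum of the
intensity profile along each ray. The half-maximum refinement removes the
residual threshold-placement bias and stays unbiased after interpolation has
smoothed an edge (as it has after reslicing). Radial (star-shaped) contours
cannot self-intersect, which keeps the later unwrapping well-defined; strongly
non-star-shaped lumina are outside the supported geometry and fall to the
fallback path.

## The media–adventitia limit

The rule has no free anatomical landmark, only geometry: Euclidean distance
maps are taken from every wall pixel to the lumen (`d_in`) and to the outer
paraffin (`d_out`); the mid-wall line is the set where both are equal, and the
media is the inner half of the wall dilated by a disk of radius
`round(0.35 × minimum wall thickness)` and clipped to the wall. On a pixel
grid an exact-equality set is empty, so the mid-wall line is realised as the
band `|d_in − d_out| ≤ 0.5 px`. The minimum wall thickness is the minimum of
`d_in + d_out` over that band; this estimator carries a discretisation
uncertainty of roughly ±0.5 px, which only matters when `0.35 × T` sits very
close to a rounding boundary. The factor 0.35 is exposed in the configuration
(`media_dilation_factor`) because it was calibrated for one mouse strain and
age range and its suitability elsewhere is unknown. The minimum is taken per
slice, not per stack — the wall of a curved vessel varies axially, and a
per-slice minimum keeps the rule local; this interpretation is logged with
each run.

The resulting media outline is smoothed as a function of angle with a cyclic
cubic regression spline (period 2π, smoothing chosen by GCV unless
`contour_spline_sp` is set), and the media mask is regenerated from the
smoothed contour. Manual corrections enter through
`apply_limit_override()`: the corrected slice's radius profile is fixed and
the profiles of all slices are re-smoothed along the axial direction by a
weighted smoothing spline strongly anchored at override slices, so one
correction readjusts its neighbourhood with decaying influence.

## Lamellae

Within the media mask only, a second automatic threshold separates the bright
lamellae from the interlamellar tissue; connected components smaller than
`min_lamella_px` (default 10 px) are discarded as noise. Lamellar,
interlamellar and media areas are integer pixel counts scaled by the squared
voxel size, so `lamellae + interlamellar = media` holds exactly on every
slice.

## Fallback for non-circular vessels

Dilated or damaged vessels can defeat the standard path (open wall,
non-annular topology). The fallback thresholds the brightest fraction of the
*tissue* intensities (default: top 15% of pixels above the wall threshold —
mainly lamellae), applies the watershed transform to the Euclidean distance
map of the complement, and takes the basin containing a seed point as the
lumen; the watershed ridge lines close the tube across moderate gaps. The
seed defaults to the lumen centroid of the nearest successfully segmented
slice (or the bright structure's centroid). Seeded enclosed-region growth
replaces the original interactive lumen carving, which is not reproducible;
every fallback slice is flagged `provenance = "fallback"`.

A closure-quality guard makes the failure mode explicit rather than silent:
after carving, at least 75% of the recovered lumen outline must lie within
5 px of bright wall structure, otherwise the slice fails with a request for a
manual mask. Walls broken across more than ~90° of arc fail this guard.
On fallback slices the media–adventitia limit is not computable
automatically, so the whole wall is reported as media and thickness is not
measured — areas and diameter only.

## Centreline, reslicing and the central window

Lumen centroids of all slices are interpolated by cubic smoothing splines
(one per in-plane coordinate, GCV smoothing by default). The stack is then
resampled on planes orthogonal to the local tangent with trilinear
interpolation at the original voxel pitch. In-plane frames are carried by
parallel transport of an initial basis, which introduces no axial twist —
important because a twisting frame would shear the en-face break map. An
obliquely cut tube shows elliptical sections (major axis inflated by
1/cos θ); reslicing removes this bias, and the tilted-tube phantom verifies
both the predicted inflation before correction and its disappearance after.

Morphometry is computed on a contiguous window of `central_window_n_slices`
(default 200) slices centred on the stack midpoint, with floor division when
the remainder is odd. Stacks shorter than the window are rejected rather than
silently analysed in full.

## Virtual opening and thickness

The polar unwrap casts a ray outward from each lumen-contour point along the
local contour normal, sampling bilinearly at unit-pixel steps; the wall
becomes a horizontal band whose depth-0 edge is the lumen–wall limit at every
angle. Normals (rather than rays from a global centre) keep neighbouring rays
from crossing over mildly wrinkled contours. The inverse mapping assigns each
Cartesian pixel to the nearest ray — testing a few neighbouring candidates by
lateral distance, since a pixel's polar angle does not identify its ray
exactly under wrinkling — and interpolates the band along depth.

Media thickness is sampled at the same `K` angles: the distance from each
lumen-contour point to the media–adventitia contour along the normal, in µm.
Rays that fail to hit the outer contour (pathological wrinkles) are dropped
and counted; a slice with more than 10% drops is flagged. The per-slice
distribution is binned with Freedman–Diaconis bins and fitted with a Gaussian
by least squares on bin centres and counts (Levenberg–Marquardt, initialised
at the sample mean and SD); the fitted mean and SD are the primary thickness
statistics, with sample moments reported alongside. Degenerate distributions
(fewer than four occupied bins) fall back to sample moments with the SD
capped by the bin width rather than fitting a curve to a spike.

Lumen diameter follows the echocardiographic convention: a direct
least-squares (Fitzgibbon) ellipse fit to the internal circumference, with
the diameter defined as the mean of the fitted major and minor axes. For a
tube tilted by θ this definition overestimates by `(1 + 1/cos θ)/2 − 1`
before reslicing (the full `1/cos θ` sits on the major axis alone).

## IEL surface and breaks

Per slice, the 1-px lumen–wall border is dilated by a disk of radius
`iel_dilation_px` (default 7 px, the radius found optimal for capturing the
entire IEL at 1.1 µm voxels) and clipped to the wall; stacking these shells
gives the IEL as a thin 3D structure. The en-face image takes, for each
(slice, angle), the maximal intensity over shell voxels along the outward
ray — axial position down the page, circumference across. Columns with no
shell voxel are marked invalid, never interpolated. The circumferential pixel
pitch is recorded per slice as `2π × mean lumen radius / K × voxel`, because
a single global pitch would bias break areas in dilated regions.

Break detection is automated: pixels below a threshold (fixed grey value, or
automatic over the valid surface) form 8-connected components, and components
of at least `min_break_area_um2` (default 20 µm²) are reported with areas
accumulated from the per-slice pitch. An automatic threshold is only accepted
when the two intensity classes it separates differ by at least
`break_min_contrast` grey levels (default 10); an intact surface has no dark
mode, and without this guard any threshold would split its noise. A manual
break mask can replace detection entirely, preserving parity with manual
contouring, and its percentage passes through exactly.

## Group statistics

Comparisons operate on one value per animal (the per-sample mean), as in
small-cohort designs with n ≈ 5. The two-sample Kolmogorov–Smirnov test uses
the exact small-sample distribution when both groups have at most 10 values —
equivalent to the exhaustive permutation tail, which the test suite verifies
against all 252 splits at 5-vs-5 — and the asymptotic formula otherwise. The
F-test compares dispersions: the larger sample variance over the smaller,
two-sided p by doubling the upper tail and capping at 1. Its normality
assumption is fragile at n = 5; this is documented rather than repaired,
because dispersion flagging under exactly these conditions is part of the
method being reproduced. Both tests are two-sided (the convention of the
original analysis software). Flags follow `*** p ≤ 0.001`, `** p ≤ 0.01`,
`* p ≤ 0.05` (boundaries inclusive) with `#` marking the 0.05–0.08 trend
band. No multiple-testing correction is applied — again by design parity —
and the number of comparisons made is attached to every table.

# The phantom: what it emulates, and what it does not

The synthetic generator renders, per slice, an annular vessel with
analytically known geometry: a wrinkled inner boundary
`r(θ) = s(z)·R + A sin(fθ)`, a wall of constant radial thickness, concentric
lamellar rings inside a media band, an adventitial rim, paraffin grey inside
and out, optional axis tilt and sinusoidal waviness, smooth focal dilations
(`sin²` ramp of the radial scale), lamellar breaks (interlamellar grey within
an angular/axial window, with ~2 px smooth circumferential edges and crisp
axial extent), occlusion artefacts that blank a wall sector, and additive
Gaussian noise clipped to the intensity range. With `noise_sigma = 0` the
clean phantom is reproduced exactly; identical spec and seed give a
bit-identical stack.

Boundaries are antialiased analytically: each radial interface receives 1-px
linear coverage blending on the radial signed distance, which is the exact
box-filter average for radially varying regions. This replaces supersampling
at equal accuracy and a fraction of the cost, and it is what makes recovery
tolerances attributable to the pipeline rather than to the phantom's
rasterisation.

Two geometric choices are worth noting. First, a tilted tube is rendered via
the true distance-to-axis metric, so in-plane sections are exact ellipses
(major axis `R/cos θ`) and sections orthogonal to the axis are exact circles;
the per-slice ground-truth table always refers to orthogonal sections.
Second, the innermost lamellar ring starts flush with the lumen border — the
IEL *is* the luminal boundary in phase contrast — and the remaining rings
span the media evenly; the placement is symmetric about the media midline, so
the true lamellar fraction reduces exactly to
`n × ring thickness / media thickness`. The phantom's media band ends where
the half-wall + 0.35-rule limit would put it, so the delineation stage is
tested against a target it can in principle hit exactly.

The phantom deliberately does not emulate: realistic adventitial texture,
intensity inhomogeneity or ring artefacts of reconstruction, non-annular
topology (other than via occlusion artefacts), vessel branch points, or the
physics of phase retrieval. Passing phantom tests therefore demonstrates
geometric and numerical correctness of the measurement chain — not robustness
to every artefact of real synchrotron data, where exclusion masks and limit
overrides exist for a reason.

Default break coverage is integrated with the same smooth-edge coverage
function the renderer uses, and the analytic en-face break area counts only
holes that reach the IEL (ring 1): deeper lamellar breaks are invisible from
the luminal surface by construction, as they are in the en-face projection of
real data. At small phantom scales a wide IEL shell can graze the second
ring, so break-recovery phantoms use wall geometries in which only ring 1
lies within the default 7-px shell — matching the relative scale of the real
scans.

# Numerical choices and degenerate inputs

- Coordinates are 1-based `(slice, row, col)` — the R convention — with
  subpixel contours as `(theta, r, row, col)` tibbles; all physical outputs
  are µm/µm² via the isotropic `voxel_size_um`.
- Connectivity: 8-connected foreground, 4-connected background (the standard
  complementary pair avoiding topological paradoxes); the 8-connected
  labelling merges diagonal neighbours on top of the library's 4-connected
  labelling.
- Structuring elements are discrete disks; the media dilation radius rounds
  to the nearest integer pixel.
- Interpolation is bilinear in-plane and trilinear through the volume —
  monotone, artefact-free for binary-adjacent data.
- Quadrature for analytic areas uses adaptive integration to a relative
  tolerance well below 10⁻⁶; in the zero-wrinkle limit it matches the closed
  annulus formula to the same precision.
- Uniform slices, contrast-free media, empty masks, walls thinner than 3 px,
  lumina touching the border, ellipse fits on collinear points, and both-zero
  variances in the F-test all raise typed errors naming the condition rather
  than returning a number.
- Per-slice failures inside a run are recorded and excluded up to a tolerance
  (default 20% of slices), after which the run aborts with per-slice
  diagnostics.

# Problem sizes

The validation experiments are sized for a single CPU: the reference recovery
phantom is 64 slices of 512×512 at 1.1 µm with a 100-px lumen radius and a
40-px wall; tilt experiments use 24 slices of 256×256; break-recovery
phantoms 24 slices of 224×224; and the synthetic ageing cohort three groups
of five stacks at 12 slices of 192×192 with group wall thicknesses of
18/20/22 px jittered by 0.8 px between samples. These reproduce the study's
design — three age groups, five animals each, monotone medial thickening, a
central analysis window, pooled per-slice thickness distributions — at desk
scale; absolute magnitudes are not those of the original scans, and no
comparison to the original animals' values is implied.

# Known limitations

- Star-shaped contour geometry: strongly lobed lumina are not representable;
  such slices route to the fallback, which reports areas only.
- The thickness estimator measures along lumen-contour normals; under extreme
  wrinkling normals may miss the outer contour locally (dropped and counted).
- The minimum-thickness estimator's ±0.5 px discretisation interacts with the
  `round()` in the dilation rule near half-integer products.
- The F-test's normality fragility at n = 5 is preserved by design.
- 32-bit float TIFF output is not written (input floats are supported); the
  internal representation is float regardless of source depth.
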