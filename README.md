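# aortamorph

Micro-scale morphometry of the murine aortic wall from phase-contrast
microCT stacks.

## What it is for

Phase-contrast micro computed tomography resolves the layered structure of
the arterial wall — elastic lamellae, interlamellar tissue, adventitia — in
intact, unstained, paraffin-embedded vessels at ~1 µm voxels. Studies of
vascular ageing and of connective-tissue disease models (e.g. Marfan-type
*Fbn1* mutants) need the classical histological parameters from such volumes,
per slice and in 3D, without manual sectioning artefacts or observer bias.

`aortamorph` is an automated, fully deterministic pipeline for that
measurement problem, aimed at researchers analysing tubular-vessel microCT
stacks:

- per-slice segmentation of **wall, lumen, tunica media and lamellae**, with
  a watershed fallback for non-circular (dilated) vessels;
- **centreline** estimation and **orthogonal reslicing**, so measurements are
  taken on true transverse cuts;
- **virtual opening** (local Cartesian→polar unwrap) of the vessel;
- per-slice **morphometry**: lumen diameter, media thickness distribution
  with a Gaussian fit, cross-sectional areas, lamellar fraction;
- **IEL surface analysis**: the internal elastic lamina extracted as a thin
  shell, projected en face, and scored for breaks as a percentage of the
  luminal surface;
- **group statistics**: two-sample Kolmogorov–Smirnov tests on per-animal
  means and F-tests of dispersion, with `*/**/***/#` flagging;
- a **synthetic aorta phantom generator** with analytic ground truth, so
  every stage is validated against known geometry.

## The method in brief

For a binary wall mask `W` with lumen `L`, the media–adventitia limit is
derived purely geometrically. With Euclidean distance maps
`d_in(x) = dist(x, L)` and `d_out(x) = dist(x, outside)` for `x ∈ W`, the
mid-wall line is `{x : |d_in − d_out| ≤ 0.5 px}`, the minimum wall thickness
is `T = min(d_in + d_out)` on that line, and

```
media = (inner half of W) ⊕ disk(round(0.35 · T)) ∩ W
```

The media outline is smoothed as a periodic spline in polar coordinates
about the lumen centroid. Media thickness is sampled at K angles along the
lumen-contour normals, its per-slice histogram fitted to a Gaussian
`A·exp(−(t−µ)²/2σ²)`; lumen diameter is the mean of the axes of a direct
least-squares ellipse fit to the internal circumference (the
echocardiographic convention); lamellar fraction is the pixel-count ratio
`100·|lamellae|/|media|`, so lamellar + interlamellar area equals media area
exactly. The IEL is the 1-px lumen–wall border dilated by 7 px, and breaks
are dark connected components on its en-face maximal projection.

## Worked example

Generate a clean synthetic aorta (16 slices, 256×256, 60-px lumen radius,
24-px wall, three lamellae, 1.1 µm voxels) and run the full pipeline on it:

```r
library(aortamorph)

spec   <- phantom_spec(n_slices = 16, slice_shape = c(256, 256),
                       lumen_radius_px = 60, wall_thickness_px = 24,
                       n_lamellae = 3, lamella_thickness_px = 3,
                       voxel_size_um = 1.1)
config <- pipeline_config(central_window_n_slices = 16)
run    <- run_morphometry(spec, config)
run
#> <morphometry_run> 16 slices (window 1..16), 0 fallback, 0 failed
#> # A tibble: 6 × 4
#>   parameter                 mean       sd     n
#>   <chr>                    <dbl>    <dbl> <int>
#> 1 lumen_diameter_um        132.  1.80e-14    16
#> 2 media_thickness_um        21.7 8.31e-12    16
#> 3 media_area_um2         10551.  0           16
#> 4 lamellae_area_um2       4622.  0           16
#> 5 interlamellar_area_um2  5929   0           16
#> 6 lamellae_pct              43.8 0           16
```

Reading the output: the fitted lumen diameter is 131.9 µm against a true
diameter of 2 × 60 px × 1.1 µm = 132 µm; the media thickness 21.7 µm against
a true media band of 22 µm; the media cross-sectional area is within 1% of
the analytic annulus area (10 644 µm²), and 43.8% of the media is lamellar
against a true ring fraction of 45%. Zero slices needed the dilated-vessel
fallback and none failed. Per-slice values live in `tidy(run)`
(`run$records`), the per-angle thickness samples in `run$thickness_samples`,
and `ggplot2::autoplot(run)` draws the per-slice traces. The same entry
point accepts a path to a multi-page TIFF stack of a real scan:
`run_morphometry("scan.tif", config)`.

IEL break analysis and cohort statistics follow the same pattern via
`run_iel()` and `run_group_comparison()`; a thin command-line wrapper with
`phantom` / `morph` / `iel` / `stats` subcommands is installed at
`inst/scripts/aortamorph.R`.

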