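---
title: "Quantifying enamel demineralisation in time-lapse micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enamel demineralisation in time-lapse micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demintrack)
```

## The measurement problem

Early enamel caries is a slow, anisotropic dissolution process: acid enters
through an exposed patch of the tooth surface and removes mineral from the
enamel, which in attenuation-contrast tomography appears as a darkening of
the affected voxels. Time-lapse synchrotron micro-CT can now image this
*in situ* at sub-micrometre voxel size with tomograms tens of minutes
apart, producing a 4D dataset: a time series of 3D greyscale stacks of the
same specimen under acid attack.

`demintrack` turns such a series into quantitative descriptions of lesion
progression. The processing chain mirrors how these experiments are
analysed in practice:

1. **Denoising** of each tomogram -- a 3D median filter followed by
   non-local means.
2. **Rigid registration** of every time point onto a chosen reference
   (the first tomogram), so that all masks and measurements live on one
   grid.
3. **Segmentation** of the total enamel region (once, on the reference)
   and of the demineralised lesion (per time point) by greyscale
   thresholding with morphological clean-up.
4. **Metrics**: per-angle radial front distances on virtual slices,
   per-slice lesion areas, lesion volumes, their normalisations, and
   demineralisation rates in physical units.

All volumes are arrays indexed `[z, y, x]` with `z` the depth from the
exposed surface; an `xy` plane is one virtual slice. One detail worth
emphasising because it differs between tools: physical extents are
computed centre-to-centre, `(n - 1) * voxel_um` for `n` voxels (see
`physical_extent_um()`), which is the convention under which the printed
extents of typical reconstructed grids (e.g. 812 voxels at 0.325 µm across
263.575 µm) are self-consistent.

## The quantity suite

For a seed point on a virtual slice and a set of angles, the *radius
distance* `d(ti)` is the Euclidean distance from the seed to the **last**
segmented lesion voxel along the ray (lesions are porous; terminating at
the first gap would systematically undercount the front). From the
per-time distances the package derives, per angle:

* `d_abs = d(ti) - d(t0)` and `d_cum = d(ti) - d(ti-1)` (µm),
* `d_acc% = (d(ti) - d(t0)) / d(ti) × 100`,
* rates `d_abs_rate = d_abs / (60 (ti - t0))` and
  `d_cum_rate = d_cum / (60 (ti - ti-1))` in µm/s, with nm/s columns.

Areas follow the same pattern per virtual slice: `Area(ti)` is the lesion
voxel count times the voxel area, normalised as `area_fd = A(ti)/A(t0)`,
`area_abs% = (A(ti) - A(t0))/A(t0) × 100`,
`area% = (A(ti) - A(ti-1))/A(ti) × 100`,
`area_fe = A(ti)/A_tote × 100` against the total enamel area of the
slice, plus absolute and cumulative rates in µm²/s. Volumes: `V(ti)`,
`v_f = V(ti)/V(t0)`, `vol% = (V(ti) - V(t0))/V(ti) × 100`,
`v_fe = V(ti)/V_tote` (a plain ratio), and rates in µm³/s and nm³/s.

Two of the percentage definitions (`d_acc%`, `area%`, `vol%`) place the
*current* value in the denominator. That is how these quantities are
printed in the experimental literature this package follows, so it is the
default; since the conventional normalisations divide by the reference or
the previous value instead, every series function accepts
`denominator = "current" | "reference" | "previous"` and labels the
default as-printed behaviour.

`edt3d()` supplies the Euclidean maps used to characterise the remaining
enamel: the exact (not chamfer) distance from each foreground voxel to the
nearest background voxel. Only background inside the volume counts, so a
half-space has an exactly linear depth profile; in the degenerate
all-foreground case the volume border is treated as background, and the
convention is documented on the function.

## The synthetic phantom and what it does (not) show

No public tomogram accompanies the experiments this package targets, so
validation rests on a synthetic dissolving-enamel phantom
(`phantom_spec()`, `generate_series()`) with exported ground truth. It
emulates the features that the measurements depend on:

* a hexagonal lattice of cylindrical rods (defaults: 5 µm diameter,
  2 µm inter-rod gap, axes along `z`), with optional positional jitter of
  the rod centres, since real enamel is ordered but not perfectly
  periodic;
* an optional denser, brighter *surface zone* slab at the exposed face;
* liquid above the face, with acid entering only through a circular
  window (everything else varnished) -- a window radius larger than the
  face exposes it fully;
* a dissolution front modelled as weighted geodesic first-arrival
  propagation from the window: each material has a speed in nm/s and the
  arrival time field is computed by Dijkstra's algorithm on the
  26-connected voxel graph with Euclidean edge lengths, which converges
  to the continuous first-arrival solution as the voxel size shrinks.
  Setting the inter-rod speed above the rod speed reproduces preferential
  inter-rod dissolution as a speed contrast -- a deliberately minimal
  mechanism, not a chemical model;
* rendering with per-class intensities in `[0, 1]`, the demineralised
  intensity overriding reached voxels, additive Gaussian noise, small
  rigid jitter drawn per frame (the reference frame is never jittered),
  and optional ellipsoidal bubble artifacts in the liquid.

Ground-truth lesion masks are nested in time by construction
(`tau <= t`), live on the reference grid (jitter affects only rendered
frames), and the whole series is a pure function of the spec including
its seed.

Default speeds (rod 1, inter-rod 2, surface zone 0.5 nm/s) sit inside the
0.54--5.58 nm/s range reported for enamel in lactic acid at pH 2.2, and
the default acquisition times are `122 + 25k` minutes, matching a first
tomogram at t0 = 122 min with ~25 min spacing. The lesion's greyscale
contrast is not quantitatively known from attenuation data alone, so the
class means are free parameters; the defaults (liquid 0.08, inter-rod
0.68, rod 0.72, surface zone 0.80, demineralised 0.30) give contrasts
large compared with realistic noise.

What passing tests on this phantom show: that the chain of filtering,
registration, segmentation and measurement returns the speeds, areas and
volumes that were put in, across the reported speed range, under noise
and inter-frame motion. What they do not show: robustness to
reconstruction artifacts (rings, beam hardening, phase fringes),
partial-volume chemistry at the lesion boundary, cracks, or deformable
specimen motion -- real data can violate assumptions the phantom
satisfies.

## Registration: design and numerical choices

The registration maximises normalised cross-correlation (NCC) over the
six rigid parameters (Euler angles about `z`, `y`, `x` in degrees;
translation in voxels) with a derivative-free Nelder--Mead search over a
three-level coarse-to-fine pyramid (block-mean factors 4, 2, 1). NCC is
chosen because it is invariant to the global intensity drop as the lesion
grows. The caller's initial guess takes the role of the manual
pre-alignment step used in practice.

Three safeguards, each motivated by a concrete failure mode observed on
phantoms, are part of the design:

* **Basin finding.** Nelder--Mead started at the identity stalls when the
  offset exceeds its initial simplex. The coarsest level therefore starts
  with an exhaustive search over integer coarse-voxel translations and a
  few rotations about `z` -- the parameter most prone to spurious optima
  on near-periodic structures -- and each level restarts the simplex once
  with tighter steps.
* **Overlap discounting and bounded translations.** NCC computed over a
  shrinking overlap can look better as content is pushed out of view;
  candidates are therefore discounted below 50 % overlap and translations
  are bounded (default ±10 voxels around the guess), which is also the
  physically plausible inter-frame motion range.
* **A weak motion prior.** A quadratic penalty
  `regularization * mean(((p - init)/5)^2)` (default strength 0.01) pulls
  parameters towards the initial guess. It only matters along directions
  the image does not constrain -- e.g. in-plane translation of a
  laterally uniform scene -- where an unregularised search performs a
  random walk; any real NCC gradient overrides it.

Because the demineralising region violates NCC's constancy assumption,
`register_rigid()` accepts an exclusion mask, and the pipeline exposes it
as `register$exclude_below_z`: everything below a given depth is ignored
by the similarity measure, leaving the liquid and the fixed liquid/enamel
surface edge (plus, on real data, any unexposed enamel) to anchor the
alignment. Without this, frames with a strongly grown lesion are pulled
several voxels in `z` towards a compromise between the surface edge and
the moving front; with it, the `z` alignment is recovered to well under
half a voxel on phantoms. The residual in-plane freedom is held by the
motion prior and is immaterial for laterally uniform phantoms.

Resampling is trilinear for intensities and nearest-neighbour for masks
(preserving binarity). Voxels that fall outside the moving volume become
`NA`, a sentinel excluded from every downstream mask and statistic; the
phantom renderer instead extends edge values ("replicate") when applying
jitter, since a physical specimen continues beyond the field of view and
a constant fill would create artificial border bands.

## Segmentation choices

Thresholding rather than model-based segmentation matches the
greyscale-drop signature of demineralisation. The enamel mask is computed
once on the reference frame (Otsu's bimodal split by default, or a fixed
value), keeps the largest 26-connected component, and fills interior
cavities; the surface zone remains inside it. The lesion threshold is
either fixed or `median - k × 1.4826 MAD` (default `k = 3`) of the
reference frame's enamel histogram -- robust location and scale are used
deliberately so that a lesion already present at the reference time
cannot drag the threshold down; this breaks down only if the majority of
the reference enamel is already demineralised, in which case a fixed
threshold should be supplied. A binary opening (radius 1 by default, with
the erosion treating out-of-volume as foreground so shapes touching the
border are not eaten) removes speckle, and only components connected to
the exposed-window seed region are kept so isolated dark spots deep in
the enamel do not count as lesion. Masks are reported as they are
measured: nesting across time is checked and warned about (default
tolerance 5 % of the previous mask) but never enforced, since each
tomogram is segmented independently.

## Ray geometry

Rays march from the seed in 0.5-voxel steps, sampling the binary slice by
nearest neighbour -- sub-voxel robustness without interpolating a binary
field. On a slice containing the depth axis (`plane = "zy"` or `"zx"`), a
ray at angle θ meets a planar front of depth `D` at distance `D/sin θ`,
so `estimate_front_speed()` accepts a per-angle projection factor
(`sin θ`) that removes this geometric inflation when a front-normal speed
is wanted, and a per-angle validity limit that discards measurements once
the front approaches the edge of the field of view.

## Problem sizes used in the validation suite

The test suite validates each operation against independent oracles
(exhaustive neighbourhood sorts, closed-form travel times, analytic
sphere/slab geometry, brute-force pixel scans) on small volumes, and the
end-to-end properties on purpose-built phantoms. The headline
end-to-end check runs the complete pipeline on a 96³-voxel homogeneous
phantom (0.325 µm voxels, eight frames 25 min apart) at front speeds
0.54, 2.0 and 5.58 nm/s and requires the mean cumulative distance rate
and the absolute volume rate to recover the configured speed and the
analytic slab rate within 10 %; registration accuracy is assessed over
20 seeded jitter trials (median error below 0.5 voxel and 0.5°);
segmentation fidelity is scored by Dice overlap against phantom truth
(exact without noise; at least 0.90/0.98 for lesion/enamel at 20 % of the
respective contrast). These sizes were chosen as the smallest at which
the phantoms still contain several rod periods and tens of voxels of
front travel, so that discretisation does not dominate the quantities
being checked.

## Known limitations

* Registration is rigid; slow specimen drift that is not rigid (swelling,
  tilt of the holder under flow) is outside the model.
* The eikonal front model ignores acid transport and chemistry; its speeds
  are phenomenological.
* The automatic lesion threshold assumes a mostly sound reference frame.
* Ray distances are defined on single virtual slices; a fully 3D radial
  analysis (cones rather than rays) is not provided.
* `area%`, `vol%` and `d_acc%` with the as-printed current-value
  denominator are not symmetric in time and can behave unintuitively for
  shrinking masks; the `denominator` switch provides the conventional
  forms.
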