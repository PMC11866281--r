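---
title: "Methods: 4D SHG feature extraction, phantoms, and the damage-mode classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D SHG feature extraction, phantoms, and the damage-mode classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shg4d)
```

## Data model and axis conventions

A measurement is a time series of two-channel z-stacks: forward- and
epi-detected SHG intensity on a common voxel grid, one stack per time
point, with `t = 0` at drug addition. Arrays are stored as
`y × x × z` (rows = y, columns = x, pages = z), matching the on-disk
multi-page TIFF layout; voxel spacings `(dx, dy, dz)` are in µm and
timestamps, in minutes, live in the manifest rather than in image
metadata. The physical convention follows how thin sections are
mounted: the *length* (glued ends, fixed) runs along y, the *width*
(outer to inner dura surface, the axis that swells) along x, and the
*height* (the ~30 µm cut thickness) along the optical axis z. This
makes "the height is unaffected by swelling" a statement about z.

## Segmentation of the joint tissue volume

All geometry derives from the forward channel, which carries the
stronger and more uniform signal; the epi channel contributes intensity
features only. The per-time-point pipeline:

1. **Smoothing**: separable 3D Gaussian, `smooth_sigma = 1` voxel.
2. **Separability guard**: the Otsu effectiveness (between-class
   variance fraction of the 256-bin histogram) must exceed
   `min_separability = 0.75`. Stacks with tissue are strongly bimodal
   (effectiveness > 0.9 down to SNR ≈ 2 on phantoms); pure noise
   fields sit near 0.6, where a threshold would carve arbitrary masks
   out of smoothed noise. Below the floor the time point is flagged
   "sample left imaging volume or signal lost" and omitted, with the
   reason recorded.
3. **Threshold**: `max(background floor, Otsu)`, both computed on this
   time point's smoothed stack. The floor is `mean + k·sd`
   (`bg_k = 4`) of the lowest-intensity quartile of border voxels —
   the quartile keeps the estimate on true background even where
   tissue touches the y-faces. Per-time-point Otsu is deliberate: the
   overall SHG intensity drifts as the drug acts, and a threshold
   frozen at baseline would eat into a fading foreground. Every
   ingredient scales linearly with intensity, so the mask is exactly
   invariant under global rescaling.
4. **Components**: 26-connected labelling; the largest component is
   the sample. Any other component whose surface lies within
   `merge_dist = 5` µm is merged — these are fiber fractions drifting
   off the main body that still belong to the sample volume. Distance
   is surface-to-surface (the dilation radius adds one voxel pitch to
   convert to centre distance).
5. **Closing and cavity fill**: morphological closing
   (`close_radius = 2` voxels), then filling of background components
   not 6-connected to the grid border. Enclosed voids count as sample
   volume: without this, the conservation signature below would be
   arithmetically impossible, because the voids between drifting
   bundles are precisely where the mean signal dilutes.
6. A minimum-size floor (`min_voxels = 500`) is applied to the
   principal component *before* closing, so a scattered noise field
   cannot be inflated into a plausible mask.

All thresholds, scales and counts are returned as provenance. A
fragment merged at 5 µm can remain physically disconnected in the
voxel grid (closing only bridges ~2·`close_radius`); the mask is still
treated as one joint tissue entity, and the number of merged
components is recorded.

## Tilt-corrected morphometry

Samples float and tilt; measuring width along grid x on a tilted slab
would overestimate it by `1/cos θ`. The principal axes come from the
eigen-decomposition of the second-moment tensor of mask voxel
coordinates. Two refinements matter in practice:

- **Grid-proximity assignment.** Axes are assigned to their nearest
  grid axis (greedy best-|dot|) and returned as (length ≈ y,
  width ≈ x, height ≈ z). For an ordinary section this equals ordering
  by descending extent; it stays correct when a wide sample's width
  exceeds the field-of-view-truncated length.
- **Degenerate-pair tie-break.** When two eigenvalues are within 20 %
  of each other (pairwise relative gap), their eigenvectors are
  replaced by the projections of the preferred grid axes onto the
  eigen-subspace. Inside such a block the in-plane orientation is
  statistically unidentifiable — interior voids or edge noise rotate
  the eigenvectors freely — and for a slab whose length and width
  spreads approach each other the projection recovers the true axes
  exactly. A cube therefore yields the identity rotation
  deterministically.

Volume is exact voxel counting, `V = n·dx·dy·dz`. Width and height are
*mean per-bin occupied extents* in the principal frame: for width, the
mask is binned on (length, height) at the voxel pitch of the nearest
grid axes and each bin contributes `max − min + 1 pitch` (closed
extent) along the width axis; height analogously over (length, width)
bins. Per-bin means are robust to ragged segmentation edges, where
bounding boxes inflate. Bins containing voxels on a grid face are
excluded from the mean (unless none remain): they are truncated by the
field of view — most visibly the obliquely cut slab ends under tilt —
and would understate the true extent. Accuracy is pitch-limited: the
staircase of an oblique boundary costs about one voxel per tilted
face, i.e. ~2–3 % on a 100 µm width at 15–20°, which is why validation
tolerances are stated in voxel pitch for small phantoms.

Intensity features are the mean `Ī` and sum `∑I` of each channel over
the mask; `∑I = Ī·n` holds exactly and is asserted on every call.
Intensity features depend only on the mask, never on the tilt
estimate.

## Trajectories, correlations, classification

Records flagged by the separability/size guards are dropped with a
reason; series are cropped at `crop_limit = 50` min (a record at
exactly 50.0 min is retained) so different drugs are compared over one
window. Percent changes are taken against the *first retained* record.
On real acquisitions that baseline lands 2–5 min after drug addition,
so any swelling faster than the mounting time is invisible to the 4D
pipeline — that regime belongs to the 2D area module. On phantoms,
timestamp grids may start at `t = 0`, which is what makes the analytic
end points (e.g. `50(1 − e^{−5})` % width gain) directly comparable.

Correlation paths pair two percent-change columns in time order and
are summarised by a least-squares slope through the origin (both
coordinates are 0 at baseline by construction) and a Pearson
correlation. The conservation arithmetic: if the cumulative signal is
conserved while the volume scales with width,
`ΔĪ% = −Δw%/(1 + Δw%/100)`, i.e. −33.3 % at +50 % width.

The classifier formalises the two damage scenarios as a pure function
of two statistics: cumulative retention `R = medianₜ ∑I(t)/∑I(t₀)`
(forward channel — the geometry channel — with epi reported alongside)
and width gain `W = max Δw%`. `R < 1 − τ_R` ⇒ intrinsic destruction
regardless of `W`; otherwise `W ≥ τ_W` ⇒ bundle drifting, else inert.
The defaults `τ_R = 0.15` and `τ_W = 10` points are calibration
choices validated on phantoms (100 % recovery over 60 randomised
phantoms in the acceptance run), not empirical constants of any
tissue. The median makes `R` insensitive to single segmentation
hiccups; the destruction rule fires on sustained loss.

Whether a cumulative signal should be summed over the filled or
unfilled mask is ambiguous in principle; this package computes it over
the filled mask (the primary definition), which is the choice under
which conservation during bundle drifting is a testable identity.

## The phantom generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

- **Geometry**: a slab of baseline width `w₀` (default 40 µm at
  1 µm pitch), height `h₀ = 30` µm (the cut thickness), infinite
  length truncated by the imaging window (glued ends), tilted by
  rotations about x and/or y (default 10° about y, the common mounting
  tilt). Generation fails, naming the first offending timestamp, if
  the tilted, swollen slab touches the x- or z-faces — mirroring how
  stack depths are chosen with a safety margin at the microscope, and
  how samples that leave the volume are omitted.
- **Swelling law**: `w(t) = w₀(1 + A(1 − e^{−t/τ_s}))`, height
  constant. The saturating exponential is a stand-in — observed curves
  saturate on tens of minutes but no functional form is established —
  so `A` and `τ_s` are free parameters, not biological inference.
- **Intensity regimes**: `inert` (constant emission); `dilution`
  (total expected emission in the envelope held exactly constant while
  ellipsoidal voids of zero emission appear progressively — the
  bundle-drifting picture); `destruction` (per-voxel emission decays
  as `e^{−t/τ_d}`). Voids are placed with a 2–2.5 µm shell inside the
  envelope and clear of the window's y-faces, so every cavity is
  genuinely enclosed — the geometry the hole-filling policy is
  designed for.
- **Channels and noise**: epi expectation = `β ×` forward (default
  0.5); Poisson shot noise at unit gain on expected counts
  (`i0 = 100` ⇒ baseline SNR ≈ 10) plus Gaussian read noise
  (sd = 2 counts), clamped at zero and rounded, so stacks are integer
  counts that round-trip bit-exactly through 16-bit TIFF. A sinusoidal
  fiber texture along the length (period 8 µm, contrast 0.3) is
  cosmetic, for segmentation robustness.
- **Scale**: default grids (96 × 64 × 48; 48 × 32 × 36 for the
  60-phantom classification benchmark) are scaled down from a real
  512 × 512 × 61 acquisition so the whole validation suite runs in
  about a minute; the physics (µm spacings, ~30 µm height, minutes)
  is kept at real scale.

What passing phantom tests shows — and what it does not: the phantoms
validate the *arithmetic* of the pipeline (conservation, tilt
correction, crop and merge rules, classifier logic) under realistic
noise. They do not contain out-of-focus haze, depth-dependent
attenuation, anisotropic PSF blur, real collagen texture, or
polarization effects; agreement on phantoms therefore bounds
algorithmic error, not total error on real tissue.

The 2D module mirrors the same philosophy for light-microscopy area
swelling at 1 frame s⁻¹: a strip phantom whose per-side half-widths
grow as `hw₀(1 + (f_S − 1)(1 − e^{−t/τ}))`. The defaults
(`f = 2.2`, `τ = 30/log 6` s) make the area ratio exactly 2.0 at
t = 30 s — the magnitude seen for the fastest-swelling case, where
the doubling happens before a first z-stack could even be recorded.
Frame classification is a transparent stand-in for interactive
pixel-classification tools: smoothed Otsu + largest component + hole
fill, with an optional seeded mode (logistic model on intensity and
local variance from labelled scribbles) for textured real images;
equivalence with any particular GUI tool's output is not claimed.
"Left/right of the original margin" is defined as the sign of the
coordinate along the frame-1 mask's minor principal axis — a stated
convention, since image left/right is arbitrary. Interval maps
(default 10 s) tile `final \ first` exactly for monotone growth.

## Numerical choices and degenerate inputs

- Otsu is computed on 256 bins after normalising by the maximum, so
  thresholding is scale-invariant to machine precision.
- Closed extents (`max − min + 1` voxel) make a one-voxel-thick
  structure 1 pitch wide, not 0.
- The rotation is re-estimated per time point (swelling changes the
  shape); per-axis tilt is reported in the QC columns so drift is
  visible.
- Empty masks, constant channels, single-voxel masks, zero-variance
  correlation inputs and sub-2-point trajectories all raise typed,
  message-bearing errors rather than returning degenerate numbers.
- Determinism: a spec (including its seed) generates bit-identical
  stacks; pipeline reruns with one config+seed produce byte-identical
  CSVs.

## Known limitations

- Width/height accuracy is voxel-pitch-limited under tilt (staircase
  bias ≈ 1 voxel per tilted face); sub-voxel boundary estimation is
  out of scope.
- The degenerate-pair tie-break prefers grid-aligned axes; a sample
  genuinely rotated in-plane *and* nearly square in length/width would
  have its in-plane rotation flattened.
- The classifier sees only (R, W); formulations that swell *and*
  destroy are called destructive by design (`R` dominates).
- No optical modelling: PSF, attenuation with depth, and
  polarization-dependent SHG response are not simulated, and no claim
  is made that phantom accuracy transfers unchanged to real stacks.
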