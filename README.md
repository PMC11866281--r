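# shg4d

4D-spatiotemporal feature extraction for second-harmonic-generation
(SHG) microscopy of collagenous tissue.

## The problem

When a drug formulation is applied topically to dense collagenous
tissue — the motivating case is the dura mater during spinal surgery —
the tissue can swell, loosen, or lose its collagen order entirely.
SHG microscopy sees fibrillar collagen directly (no label), so a time
series of two-channel z-stacks (forward- and epi-detected) recorded
after drug addition captures both the *geometry* of the sample and the
*state* of its collagen. `shg4d` turns such a series into quantitative
trajectories and a damage-mode call. It is aimed at microscopists and
image analysts who have stack time series (as TIFFs plus a manifest)
and want a transparent, scriptable alternative to GUI reconstruction
tools.

The pipeline per time point:

1. **Segmentation** of the joint tissue volume from the forward
   channel: Gaussian smoothing, per-time-point Otsu threshold with a
   border-background floor, 26-connected components with a 5 µm merge
   distance for drifting fragments, morphological closing, and 3D
   cavity filling — enclosed voids count as sample volume.
2. **Tilt-corrected morphometry**: principal axes from the mask's
   second-moment tensor; volume `V` by exact voxel counting; mean width
   `w` and mean height `h` as means of per-bin occupied extents in the
   principal frame (length ≈ y, width ≈ x, height ≈ z).
3. **Intensity features**: mean `Ī` and cumulative `∑I` SHG signal over
   the mask, per channel, with `∑I = Ī · n` exactly.
4. **Trajectory**: percent changes vs the first retained record,
   cropped to a 50 min window; 2D correlation paths such as
   (Δw%, ΔĪ%) and (Δw%, Δ∑I%).
5. **Mode of action**: with retention `R = medianₜ ∑I(t)/∑I(t₀)` and
   width gain `W = max Δw%`,
   - `intrinsic_destruction` if `R < 1 − τ_R` (collagen order lost:
     mean *and* cumulative signal fall),
   - `bundle_drifting` if `R ≥ 1 − τ_R` and `W ≥ τ_W` (fiber bundles
     drift apart: voids form, `Ī` falls, `∑I` is conserved),
   - `inert` otherwise. Defaults: `τ_R = 0.15`, `τ_W = 10` points.

Because real raw data of this kind are rarely shareable, the package
ships a phantom generator (`phantom_spec()`, `generate_stack_series()`)
producing tilted swelling slabs with analytic ground truth
(`ground_truth()`): width follows `w(t) = w₀(1 + A(1 − e^{−t/τ_s}))`
with constant height, under three intensity regimes (inert /
signal-conserving dilution with voids / per-voxel decay), correlated
forward+epi channels and shot/read noise. A companion 2D module
(`phantom_spec_2d()`, `area_trajectory()`) covers light-microscopy area
swelling at 1 frame s⁻¹ for processes faster than stack acquisition.

## Worked example

Simulate a bundle-drifting (dilution) phantom and analyse it:

```r
library(shg4d)
spec <- phantom_spec(mode = "dilution", amplitude = 0.5, tau_s = 10,
                     timestamps = seq(0, 50, length.out = 6), seed = 7)
ser  <- generate_stack_series(spec)
traj <- build_trajectory(ser)
as.data.frame(traj)[, c("timestamp","w","h","dw_pct","dh_pct",
                        "dIbar_f_pct","dIsum_f_pct")]
#>  timestamp     w     h dw_pct dh_pct dIbar_f_pct dIsum_f_pct
#>          0 39.69 29.75   0.00   0.00        0.00        0.00
#>         10 52.27 29.67  31.69  -0.25      -23.90        0.13
#>         20 57.14 29.85  43.96   0.35      -30.26        0.00
#>         30 57.01 29.79  43.61   0.15      -32.29        0.03
#>         40 59.42 29.93  49.69   0.62      -32.94        0.18
#>         50 59.62 29.82  50.21   0.22      -33.16        0.17

classify_mode(traj)
#> <mode_of_action> bundle_drifting (retention R = 1.001,
#>                  width gain W = 50.2%; tau_R = 0.15, tau_W = 10)

correlate_features(traj, "dw_pct", "dIsum_f_pct")
#> <feature_correlation> dIsum_f_pct vs dw_pct: slope 0.002, r = 0.544 (6 points)
```

Reading: the width swells +50 % while the height stays flat; the mean
forward signal falls to −33 % — exactly `−Δw/(1+Δw)` — while the
cumulative signal stays within 0.2 % of baseline (slope ≈ 0 against
width gain). That conservation signature is what separates bundle
drifting from intrinsic collagen destruction, where `∑I` collapses
with `Ī`.

On-disk workflows use `write_stack_series()` / `read_series()`
(multi-page TIFF pairs + CSV manifest) and `run_phantom()` /
`run_4d()` / `run_area2d()` with a `run_config()` (YAML-loadable; see
`inst/scripts/shg4d.R` for a command-line wrapper).

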