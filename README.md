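# gelrelease

Quantitative-MRI analysis of protein release from injectable,
thermosensitive hydrogels.

Local drug delivery to the brain can bypass the blood–brain barrier by
injecting an in situ gelling depot loaded with a therapeutic protein. To
follow the release non-invasively, the protein is labelled with gadolinium
(here a Gd-albumin conjugate, ~74 kDa, the model cargo), so that its local
concentration shortens the longitudinal relaxation time T1 of the
surrounding water. Serial T1 mapping of a gel-filled tube (in vitro) or an
injected brain depot (in vivo) then yields the full release time course,
with the gel volume tracked on the same images so swelling or shrinkage
does not masquerade as release.

`gelrelease` implements that pipeline as composable, pipe-friendly R
functions, and ships a synthetic phantom generator with exactly known
ground truth so every step can be validated end to end.

## The model

**Look-Locker T1 mapping.** After one inversion pulse, a train of
small-flip-angle readouts (flip α, spacing TR) samples the recovery. The
magnitude signal in each voxel follows

    S(t) = | A − B exp(−t / T1*) |,   A = M0*,  B = M0 + M0*

with an effective relaxation time `1/T1* = 1/T1 − ln(cos α)/TR`. A
voxel-wise three-parameter fit (with magnitude-polarity restoration)
yields A, B, T1*, and the true T1 follows from

    T1 = T1* (B/A − 1).

**Relaxivity and concentration.** A paramagnetic agent adds to the
relaxation rate R1 = 1/T1 in proportion to its concentration,
`R1 = R1(0) + r1·[CA]`; the slope r1 (mM⁻¹ s⁻¹) is calibrated from a
concentration ladder and inverted to convert R1 differences (labelled
minus blank) into concentration maps.

**Volume-corrected release.** With C(t) the mean gel concentration and
V(t) the segmented gel volume (region growing from a seed voxel, ROI core
eroded 2 voxels from the rim),

    release(t) = 100 · (1 − C(t)·V(t) / (C(t1)·V(t1))) %

relative to the dose at the first MRI time point t1; the apparent release
holds V at V(t1).

**Kinetics.** Early diffusion-controlled release from a slab scales with
√t (slope k, % h^-1/2). Inverting the early-time Fickian relation
`Mt/M∞ = 4 √(D·t / (π·L_d²))` (diffusional thickness L_d = 2L for a gel
releasing through its top face only) yields the diffusion coefficient D.
The rubber-elasticity mesh size `ξ = (RT / (G′·N_A))^(1/3)` from the
rheological plateau modulus G′ classifies the release regime: diffusive
when the cargo's hydrodynamic diameter (albumin: 7.2 nm) is below ξ.

## Worked example

A noiseless swelling tube phantom (40 µL gel slab, L = 5.5 mm, under
supernatant; D = 7×10⁻¹¹ m² s⁻¹), pushed through the full pipeline:

```r
library(gelrelease)

bundle <- run_pipeline(list(seed = 1L, phantom = list(
  dim = c(10L, 10L, 24L), voxel_mm = c(0.5, 0.5, 0.5),
  times_h  = c(1.5, 3, 6, 12, 24),
  volume_uL = c(40, 42, 46, 50, 54),
  D_true = 7e-11, sigma = 0)))

bundle$in_vitro$release
#>   time_h volume_uL     conc_mM release_apparent_pct release_corrected_pct
#> 1    1.5        40 0.008416117              0.00000              0.000000
#> 2    3.0        42 0.007536122             10.45606              5.978863
#> 3    6.0        46 0.006262011             25.59500             14.434253
#> 4   12.0        50 0.004955960             41.11345             26.391817
#> 5   24.0        54 0.003538432             57.95648             43.241243

bundle$rate_fit
#> <rate_fit> k = 11.77 % h^-1/2, intercept = -14.4 %, R^2 = 1 (window 0-24 h, corrected release)

bundle$mesh
#>   G_prime_pa    T_K mesh_nm diameter_nm   verdict
#> 1   2999.581 310.15 11.2597         7.2 diffusive
```

Reading the output: the gel swells from 40 to 54 µL while the measured
gel concentration falls. The apparent (concentration-only) release at
24 h, 58 %, overstates the true mass loss; the volume-corrected release,
43.2 %, matches the phantom's known Fickian ground truth to numerical
precision. Release is linear in √t (R² ≈ 1) with rate constant
k = 11.8 % h^-1/2, and the mesh size recovered from the synthetic
rheology trace (plateau G′ ≈ 3000 Pa) is 11.3 nm — larger than albumin's
7.2 nm diameter, so the diffusive-release verdict follows. Plot methods
(`autoplot()` on release series, rate fits, rheology traces and IVIVR
tables, `plot_t1_slice()` on maps) display each result.

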