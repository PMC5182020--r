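# saxsdose

Quantitative radiation-damage analysis for solution small-angle X-ray
scattering (SAXS).

Biological SAXS samples sit in a thin quartz capillary and are slowly
destroyed by the beam: radiolysis radicals drive aggregation (low-angle
intensity rises), fragmentation (it falls) or unfolding (the radius of
gyration grows). `saxsdose` is for beamline scientists and SAXS
experimenters who want to (a) know the absorbed dose their static sample
received, frame by frame, and (b) locate the point in the frame series
where radiation damage became statistically significant — and use that
point to rank radioprotectant additives.

The package has two halves:

**Dose engine.** The liquid column is a voxelized cylinder (axis *x*, beam
along *z*). The sample's atomic inventory is built from the recipe —
protein mg ml⁻¹ (sequence or residue count; average residue masses
110.0 / 339.5 / 327.0 Da for protein / RNA / DNA), buffer solutes, water at
55.555 mol L⁻¹ filling the residual volume — and converted to linear
coefficients μ_abs (photoelectric) and μ_att (photoelectric + Compton +
Rayleigh) from a bundled per-element cross-section table. The capillary
wall attenuates the incident flux once, by Beer–Lambert
I/I₀ = exp(−(μ/ρ) ρ t) with the mass-fraction mixture rule for μ/ρ. Per
frame and voxel, the deposited energy is
fluence × E_photon × (1 − e^(−μ_abs ℓ)), and the per-frame
**diffraction-weighted dose** (DWD) is the fluence-weighted mean of the
cumulative voxel doses. Beam profiles come from measured aperture scans
(spline-reconstructed 2-D profile) or analytic Gaussian/top-hat models.

**Damage statistics.** Two frames are compared by the CorMap test: the
sign vector of their pointwise difference is a fair-coin sequence under
the null of similarity, and the longest same-sign run *C* is scored with
the exact longest-run (Schilling) tail probability
p = P(longest run ≥ C) = 1 − 2 F_{C−1}(n)/2ⁿ. Damage onset is the first
of three consecutive frames dissimilar (p < 0.01) from frame 1; the
cumulative DWD there is the threshold dose D_t. The **RDOT** metric ranks
additives as median D_t (protected) / median D_t (unprotected), and the
signal-reduction metric is 1 minus the mean protected/unprotected
intensity ratio over the first 20 low-q points. Three visualizations
(pairwise correlation map, C-vs-frame scatter, all-pairwise heat map) show
where a run is damaged and which frame ranges can still be merged.

A seeded synthetic generator (sphere form factor + programmed damage mode
+ Gaussian noise) provides frame series with known onset frames and
effect sizes, so the whole pipeline is testable end to end.

## Worked example

Generate a 120-frame run with damage programmed at frame 8, attach a
0.57 kGy/frame dose table, and analyse it:

```r
library(saxsdose)

g <- generate_series(damage_scenario(onset_frame = 8), seed = 1)
write_series(g, "demo_frames")

summary <- run_experiment(list(
  sample_frames     = "demo_frames",
  dose_per_frame_kgy = 0.57,
  alpha = 0.01, k_consecutive = 3,
  output_dir = "demo_report"))
```

The summary (also written to `demo_report/summary.json`) reads:

```
$ preflight_ok       : logi TRUE
$ onset_frame        : int 9
$ threshold_dose_kgy : num 5.13
$ final_dose_kgy     : num 68.4
$ dissimilar_fraction: num 0.941
```

The first three frames were mutually similar (the pre-flight gate), and
the first run of three consecutive dissimilar frames starts at frame 9 —
one frame after the programmed onset, because frame 8's low-q rise is
still inside the noise — giving a threshold dose of
9 × 0.57 = 5.13 kGy. The per-frame table behind this:

```r
head(compare_to_reference(g$series), 9)
#  frame   n  C            p classification
#      2 300 12 6.853485e-02     borderline
#      3 300  7 9.119731e-01     borderline
#      ...
#      8 300 10 2.500855e-01     borderline
#      9 300 19 5.396524e-04     dissimilar
```

Dose-side pieces work standalone; a 50 µm fused-quartz wall (1.8 mm outer,
1.7 mm inner diameter) at 12.5 keV transmits

```r
transmission_fraction(quartz_capillary_wall(50), 12.5)
# [1] 0.8957988
```

and three protected vs three unprotected repeats combine into an RDOT
ranking:

```r
rdot(c(18.2, 21.1, 19.9), c(3.99, 4.56, 4.56))
# <rdot: 4.36 (median 19.9 / 4.56 kGy, n = 3/3)>
```

`demo_report/` also contains the three plots
(`cormap_first_last.png`, `reference_scatter.png`,
`pairwise_heatmap.png`) and tidy CSVs of every comparison.

A thin command-line wrapper ships at `inst/cli/saxsdose.R`
(`crop`, `cormap`, `onset`, `rdot`, `synth`, `run` subcommands).

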