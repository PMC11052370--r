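# dxduo

Analysis toolkit for **dual-labeled diffracted X-ray blinking (DXB) and
tracking (DXT)** experiments, in which two nanocrystal probes — gold and
zinc oxide — attached to different domains of a single protein are recorded
simultaneously on a photon-counting detector, so the motions of the two
domains can be compared under identical conditions.

It is written for beamline users and analysts who have (or simulate)
time-resolved diffraction movies or pre-tracked spot trajectories and want
per-domain molecular-motion statistics:

* **Geometry** — predict Au/ZnO Debye–Scherrer rings from lattice constants
  (Au fcc a = 4.08 Å; ZnO wurtzite a = 3.25 Å, c = 5.2 Å), build masked
  annular ROIs, and route every pixel or spot to a unique probe ring.
* **Blinking (DXB)** — per-pixel intensity autocorrelation
  `ACF(τ) = ⟨I(t)I(t+τ)⟩ / ⟨I(t)²⟩`, exponential fits
  `ACF = k + A·exp(−T·τ)` with the acceptance rule k > 0, A > 0, T > 0,
  weighted averaged-curve fits, five-number box statistics, two-Gaussian
  low/high-mobility decomposition, exact/tie-corrected Wilcoxon rank-sum
  comparisons, and the first-half vs second-half radiation-damage check.
* **Tracking (DXT)** — spot detection with sub-pixel centroids,
  nearest-neighbor linking with gap memory, twisting/bending (χ/θ) angular
  decomposition, lifetime filtering, temporal MSD with the
  anomalous-diffusion fit `δ²(t) = D_α·t^α + 2β²`, and θ–χ motion maps with
  projections, peak/FWHM readouts, subtraction maps and hotspot
  superposition.
* **Synthetic data** — seeded generators for blinking movies (rotational
  random walks through a Gaussian rocking curve, Poisson photons) and
  Laue-spot trajectories with known ground truth, so every pipeline stage
  is testable without beamline data.

Results flow as tibbles; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures.

## Worked example

Predict the dual-probe ring layout at 17.7 keV, then compare a ligand-free
decay-constant sample against a ligand condition that shifts weight into
the low-mobility group:

```r
library(dxduo)

geom <- detector_geometry(n_rows = 195, n_cols = 487, pixel_pitch_mm = 0.172,
                          beam_center_px = c(97, 243), distance_mm = 95,
                          frame_interval_s = 0.0125)
rings <- standard_ring_set(beam_spec(17.7), geom)
rings[["Au(111)"]]
#> <ring_roi> Au(111): d = 2.3556 Å, radius = 169.93 px ± 2, 1652 pixels
rings[["ZnO(101)"]]
#> <ring_roi> ZnO(101): d = 2.4753 Å, radius = 161.18 px ± 2, 1672 pixels

sample_free <- generate_decay_samples(mu = c(0.06, 0.13), sd = c(0.012, 0.025),
                                      w = c(0.5, 0.5), n = 4000, seed = 1)
sample_lig  <- generate_decay_samples(mu = c(0.06, 0.13), sd = c(0.012, 0.025),
                                      w = c(0.68, 0.32), n = 4000, seed = 2)

decay_stats(sample_free$value)
#> # A tibble: 1 × 6
#>      min    q25 median   q75   max     n
#> 1 0.0226 0.0599 0.0860 0.131 0.207  4000

fit_two_gaussians(sample_lig$value)
#> <gaussian_pair> group-I: 67.7% (mu 0.06028, sd 0.01192); group-II: 32.3% (mu 0.1304, sd 0.02511)

compare_distributions(sample_free$value, sample_lig$value)
#> # A tibble: 1 × 6
#>   statistic  p_value method tier    n_a   n_b
#> 1  17456493 4.89e-45 normal ***    4000  4000
```

Reading the output: the two probe rings sit ~9 px apart, so a 2 px
assignment tolerance separates them cleanly. The ligand-free sample has a
median decay constant of 0.086 /s; the ligand sample's histogram decomposes
into 67.7% low-mobility (group-I) area versus the generating 68%, and the
rank-sum test flags the distribution shift at the `***` (p < 0.001) tier.

End-to-end movie workflows are driven by `run_dual_dxb()` (stacks →
per-ring decay statistics, mixtures, condition comparisons) and
`run_dual_dxt()` (stacks or trajectory tables → per-ring angular
trajectories, MSD fits, motion maps, subtractions, hotspots), configured by
a YAML geometry file (see `inst/extdata/example_geometry.yaml`). The
methods vignette (`vignettes/dual-probe-methods.Rmd`) documents the models,
conventions and numerical choices.

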