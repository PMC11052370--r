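---
title: "Dual-probe blinking and tracking analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-probe blinking and tracking analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxduo)
```

# The two observables

A protein carrying two nanocrystal probes — gold on one domain, zinc oxide
on another — scatters X-rays into probe-specific patterns on a
photon-counting detector, and the time structure of those patterns reports
each domain's motion independently.

**Blinking (DXB).** Under a monochromatic beam, each probe contributes to a
Debye–Scherrer ring, and a ring pixel's photon count blinks as crystals
rotate through the Bragg condition. The per-pixel intensity autocorrelation

$$\mathrm{ACF}(\tau) = \frac{\langle I(t)\, I(t+\tau)\rangle}{\langle I(t)^2\rangle}$$

is fitted with $k + A e^{-T\tau}$; the decay constant $T$ (1/s) grows with
rotational mobility. Pooling $T$ over all ring pixels gives a mobility
distribution per probe.

**Tracking (DXT).** Under a pink (broad-bandwidth) beam, each crystal gives
a Laue spot whose on-detector trajectory decomposes into twisting
($\chi$, azimuthal) and bending ($\theta$, diffraction-angle) components.
Per-trajectory temporal mean squared displacements are fitted with the
anomalous-diffusion model

$$\delta^2(t) = D_\alpha t^{\alpha} + 2\beta^2,$$

where $\alpha < 1$ marks subdiffusion, $\alpha > 1$ superdiffusion, and
$\beta$ absorbs localization error.

Because the Au and ZnO lattices differ (fcc $a = 4.08$ Å vs wurtzite
$a = 3.25$ Å, $c = 5.2$ Å), their rings and spots are geometrically
separated and the two domains can be analyzed side by side from one
recording.

# Geometry conventions

* Pixels are 0-based `(row, col)`; a pixel's center sits at integer
  coordinates and all radii are measured to pixel centers.
* Ring prediction is Bragg's law plus a flat-detector projection,
  $r = L \tan(2\theta_B)/p$ with sample–detector distance $L$ and pixel
  pitch $p$. No polarization, solid-angle or distortion corrections are
  applied — the decay-constant and trajectory statistics are insensitive to
  smooth intensity scalings.
* Ring ROIs are annuli of configurable half-width (default 2 px) minus
  user-supplied rectangular masks. Masks are always explicit in the config
  because intermodule gaps are installation-specific.
* Under a pink beam of fractional bandwidth $b$, a reflection is accepted
  anywhere between the radii predicted at $E(1 \pm b/2)$; ring assignment
  widens its window accordingly.
* `assign_ring()` refuses ambiguity: if two candidate rings match within
  tolerance it raises an error rather than guessing. Inside the workflow
  drivers an ambiguous trajectory is tallied as unassigned instead, so a
  single borderline spot cannot abort a run.

At 17.7 keV with the tracking geometry (95 mm, 172 µm pixels) the six
indexed rings — Au (111), (200) and ZnO (100), (002), (101), (102) — are
separated pairwise by more than 8 px, so a 2 px assignment tolerance routes
every observation uniquely.

# Blinking estimators

**ACF estimator.** For lag $m$ the numerator averages the $n - m$ available
products while the denominator is the full-trace mean of $I^2$, which
matches the normalization above literally and makes $\mathrm{ACF}(0) = 1$
exactly. The default maximum lag is $n/4$ frames; longer lags are
pair-starved. The $\tau = 0$ point is excluded from fitting (it carries no
decay information, being 1 by construction).

**Exponential fit.** Nonlinear least squares (Levenberg–Marquardt) with the
data-driven start $k_0 = \min \mathrm{ACF}$, $A_0 = \mathrm{ACF}(\tau_1) -
k_0$, and $T_0$ from the lag at which the curve falls to $A_0/e$; five
deterministic starts spread the decay-rate guess over two decades. A pixel
fit is *accepted* only when it converged with $k > 0$, $A > 0$ and $T > 0$;
everything else is flagged, counted, and excluded from downstream
statistics — never raised as an error. All-zero (dead) pixels are excluded
and tallied separately.

**Averaged curves.** The pixel-averaged ACF is fitted by weighted least
squares with weights $1/\mathrm{SE}^2$ from the across-pixel standard error
per lag; zero-SE lags receive the largest finite weight present.

**Distribution statistics.** Box summaries use type-7 (linearly
interpolated) quantiles, the most common convention. The two-Gaussian
mobility decomposition is a least-squares fit of two Gaussian curves to the
histogram bin counts (Freedman–Diaconis binning by default, overridable),
with components ordered so group-I is the low-mobility (smaller-mean)
component and area percentages computed analytically from
$a_i \sigma_i \sqrt{2\pi}$ — they sum to 100 exactly by construction.

**Comparison test.** Two-sided Wilcoxon rank-sum with midrank ties: exact
enumeration of all group assignments when $n_a + n_b \le 12$, otherwise the
normal approximation with tie correction. Tiers: `***` $p<0.001$ (the
reporting threshold), `**` $p<0.01$, `*` $p<0.05$, else `n.s.` — the finer
tiers are conventional additions.

**Radiation-damage check.** The movie is split at the midpoint
(first $\lceil n/2\rceil$ frames vs the rest), the full
ACF → fit → distribution chain runs on each half, and the two accepted-$T$
distributions are compared; $p < 0.001$ raises the damage flag.

# Tracking estimators

**Detection and linking.** Spots are local maxima of the
background-subtracted frame (median background by default) above a
threshold, refined to sub-pixel by an intensity-weighted centroid in a
±3 px window; a second suppression pass on the refined centroids removes
shoulder-noise duplicates. Linking is greedy nearest-neighbor with a
maximum displacement (default 5 px) and gap memory (default 2 frames).
Crossing-track disambiguation is out of scope; the simulations used for
validation are constructed non-crossing, and real crossings will fragment
or swap tracks as with any local linker.

**Angular decomposition.** Per step, $\Delta\chi$ is the signed azimuthal
displacement about the beam axis (wrapped to $(-180°, 180°]$) and
$\Delta\theta = \tfrac12\,\Delta(2\theta_{\mathrm{scatter}})$ with
$2\theta_{\mathrm{scatter}} = \arctan(r_{\mathrm{mm}}/L)$. The factor
$\tfrac12$ reflects that a crystal tilt of $\delta$ deflects the
Bragg-reflected ray by $2\delta$; the convention is recorded in each
histogram's metadata because the two axes are named but not operationally
defined in the source experiments.

**MSD and fit.** The temporal MSD uses lags up to $n/4$; the
anomalous-diffusion fit runs with bounds $D_\alpha \ge 0$,
$\beta^2 \ge 0$, $\alpha \in [10^{-3}, 5]$, initialized from a log–log
regression. Estimates with $|\alpha - 1| \le 0.05$ are labeled `normal`;
the strict sub/superdiffusion inequalities apply outside that band (a
noiseless $\alpha = 1$ curve would otherwise be classified by floating-point
accident). Identically zero curves are labeled `stationary`. Both
per-trajectory fits and an ensemble-averaged-curve fit are provided;
per-trajectory is the default for maps, the ensemble curve is the robust
route to a population diffusion constant (per-trajectory $D_\alpha$ has a
heavy tail because $D$ and $\alpha$ errors trade off).

**Motion maps.** Each trajectory contributes one $(S_\chi, S_\theta)$
point; the default statistic is $\log_{10}$ of the temporal MSD at lag 1
frame per axis. What quantity the source experiments binned on these axes
is the largest inferential gap in this reimplementation, so the statistic,
lag and units are embedded in every histogram's metadata, and alternatives
(net displacement, $D_\alpha$) are selectable. Binning defaults to 50×50
bins over the 1st–99th percentile of the pooled statistics; all comparison
operations (subtraction, hotspot superposition) require bitwise-shared
edges and refuse to resample. Densities are normalized to unit sum, so
subtraction maps sum to zero exactly. Hotspots are occupied bins above a
density quantile (default 0.90) and are compared by density-weighted
centroids. 1-D peak positions use three-point parabolic refinement (skipped
on plateaus, where the leftmost maximal bin is reported with a warning);
FWHM interpolates the half-maximum crossings linearly, reporting one bin
width for a single occupied bin.

# The synthetic-data generator

No beamline data ship with this package, so every stage is validated
against generators whose ground truth is known.

**Orientation walks.** Each crystal's tilt and twist perform independent
Gaussian random walks with per-step variance $2 D_{\mathrm{rot}}\Delta t$
(small-angle planar approximation, which keeps the two axes independent by
construction and matches the two-axis decomposition used in analysis; no
full SO(3) diffusion). Optionally the walk is mean-reverting
(Ornstein–Uhlenbeck) with relaxation time $\tau_r$: a pure Brownian tilt
drifts off the rocking curve, so the movie dims over time and the blinking
process is nonstationary — which would confound the first-half/second-half
damage null. Blinking simulations therefore default to
`relax_s = "auto"`, i.e. $\tau_r = w^2 / D_{\mathrm{rot}}$ per crystal so
the stationary tilt spread equals the rocking width $w$ and faster-rotating
crystals decorrelate faster, as the analysis assumes.

**Blinking transfer.** A crystal at tilt $x$ contributes expected counts
$\mu \exp(-x^2/2w^2)$ (Gaussian rocking-curve proxy; the experiments state
no mosaicity model) plus a flat background, Poisson-sampled per frame —
photon-counting detectors have no read noise. For the stationary OU walk
the intensity ACF has the closed form

$$\mathrm{ACF}(\tau) = \frac{\sqrt{1+2a}}{\sqrt{(1+a)^2 - a^2
e^{-2\tau/\tau_r}}}, \qquad a = D_{\mathrm{rot}}\tau_r / w^2,$$

implemented as `dxb_theoretical_acf()`. Poisson noise and background
rescale the positive-lag curve by constants and leave the decay rate
untouched, so an exponential fit to this analytic curve is the independent
truth that the noisy pixel pipeline is checked against.

**Simulation regimes.** Blinking validation uses the recording protocol of
the experiments (100 ms frames, 2000 frames) with a rocking width of 30°,
50 expected photons at exact Bragg, 0.5 background counts, a ~270-pixel
Au(111) ROI on a 64×64 detector cutout, and fits over lags up to 10 s.
The 30° width is matched to the prescribed rotational-diffusion grid
(0.01–1 rad²/s) so that decay constants span ~0.1–8 /s across it — the
slow end reproducing the ~0.1 /s scale of published cellular
measurements. Tracking validation uses 12.5 ms frames and 5000 frames with
Au(111) and ZnO(100) rings on a 160×160 cutout, $D_{\mathrm{rot}} =
10^{-6}$ rad²/s, 200-photon spots with a 1.2 px Gaussian PSF, and 150
trajectories per ring with geometric lifetimes (mean 150 frames). Spots are
placed at golden-angle azimuth strides with births staggered by index, so
simultaneously alive spots are widely separated — the non-crossing regime
the linker is specified for. These problem sizes are the package's
validation choices: large enough that Monte-Carlo bounds are meaningful,
small enough that the whole suite runs on a laptop.

**What the generator does not emulate.** Detector flat-field structure,
dead time, gain dispersion and module gaps' edge effects; diffuse cellular
and buffer scattering beyond a flat term; probe-size heterogeneity;
crossing trajectories; energy-resolved Laue structure. Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every instrumental artifact of real
recordings.

# Workflow drivers and reporting

`run_dual_dxb()` analyzes each ring group per condition (ZnO rings pooled
by default, as in published blinking analysis; Au separate) and compares
every condition against the first-named baseline. `run_dual_dxt()` routes
trajectories to rings, filters by lifetime, fits MSDs and builds motion
maps on edges shared across conditions, producing baseline subtractions, a
treatment-vs-recovery subtraction, and hotspot reports per ring. Both
return reports whose counts reconcile exactly
(accepted + rejected + degenerate = attempted) and never drop data
silently.

Every generator is bit-reproducible given its seed and restores the global
RNG state. File formats are plain: multi-page 16-bit TIFF stacks, CSV
trajectories and incident-intensity series, YAML geometry configs, JSON
audit exports. The beam energy must be stated explicitly in the config —
no default is assumed for monochromatic recordings.

# Known limitations

* The linker is local and greedy; dense or crossing spot fields need a
  global assignment method out of scope here.
* Per-trajectory $D_\alpha$ estimates are heavy-tailed; use the ensemble
  fit for population diffusion constants.
* The motion-map axis statistic is a documented choice, not an
  experimentally pinned definition; compare maps only within one statistic.
* HDF5 input is not supported; convert to multi-page TIFF or pass arrays
  and CSVs directly.
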