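---
title: "Models and methods: simulating and analysing hindered lipid diffusion with FCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing hindered lipid diffusion with FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidfcs` is built around one question: how do nanoscale hindrances —
transient trapping by molecular complexes, and meshwork compartmentalisation
with rare hops across boundaries — change what fluorescence correlation
spectroscopy (FCS) reports about lipid diffusion in a membrane? The package
provides the forward model (a particle Monte Carlo simulator with a Gaussian
detection spot), the measurement stack (multi-tau correlation, 2D FCS model
fitting, scanning-FCS carpets), the population statistics (log-normal
transit-time mixtures selected by BIC), and a small image-analysis utility
(liquid-ordered partitioning, %Lo). Everything is exercisable end to end on
synthetic data with known ground truth.

```{r setup}
library(lipidfcs)
```

## The simulator

`sim_config()` defaults encode the study conditions the package reproduces:
350 particles moved every 1 microsecond with microscopic diffusion
coefficient D = 1 um^2/s on a 3 um domain for 20 s, probed by a 250 nm
Gaussian spot at the centre. Free mode displaces each particle by
independent per-axis Gaussian increments of standard deviation
sqrt(2 D dt). Trapped mode adds a two-state Markov chain per particle:
before each displacement a mobile particle is immobilised with probability
p_trap = 5e-5 per step and a trapped one released with probability
p_untrap = 5e-5; trapped particles stay fluorescent. The stationary trapped
fraction is p_trap / (p_trap + p_untrap) (one half at the defaults), so the
long-time diffusion coefficient halves. Hop mode tiles the domain with a
Voronoi meshwork whose characteristic size — defined as the square root of
the mean compartment area — is 110 nm, built from a uniform Poisson process
of seed points with density 1/mesh_size^2; a proposed step that would change
compartment is accepted with probability p_hop = 0.05 and otherwise
rejected.

Design choices that the source description leaves open, and how this
package resolves them:

* **Domain geometry.** "A circle wrapped around at the edges" is not a
  well-defined manifold; periodic wrapping of a disc cannot preserve
  uniform density. The default domain is therefore a periodic square
  (torus) of side 3 um, which preserves density and the stated length
  scale; a circular domain with antipodal re-entry is available via
  `domain_shape = "circle"`.
* **Spot convention.** The observation size is interpreted as the
  full width at half maximum; the 1/e^2 radius used by the detection
  profile is w0 = FWHM / sqrt(2 ln 2) ≈ 212 nm. The convention is a tagged
  field (`spot_convention`) so 250 nm can alternatively be read as w0.
* **"Bounce off" at compartment boundaries** is implemented as move
  rejection — the particle simply keeps its position for that step. This
  is the standard lattice-free approximation: it is unambiguous at Voronoi
  edges and preserves detailed balance within a compartment. True specular
  reflection would require resolving edge geometry at every rejected
  crossing for no measurable difference at 1.4 nm steps.
* **Trap timing.** Trap/untrap is evaluated before displacement, and a
  newly released particle moves in the same step. Fixing the order makes
  trajectories reproducible bit-for-bit.
* **Detection.** The intensity is sum(exp(-2 r^2 / w0^2)) over particles,
  with minimum-image distances on the torus and contributions beyond 3 w0
  (under 2e-8 of the peak) truncated. Photon (Poisson) noise is off by
  default — the simulated "apparent intensity" is noiseless — and can be
  switched on for realism tests.
* **Random numbers.** The hot loop uses a single xoshiro256++ stream with
  Marsaglia-polar Gaussians, seeded from R's RNG, so `set.seed()` (or
  `config$seed`) fixes the whole trajectory while keeping paper-scale runs
  (~10^9 draws) affordable. The compartment lookup uses an exact
  nearest-seed table rasterised at ~mesh/8 resolution; each raster cell
  stores every seed that can be nearest to a point inside it, so lookups
  are exact, not approximate.

## Correlation

`autocorrelate()` implements the multi-tau scheme: lags 1..2m samples at
full resolution, then the trace is halved by averaging adjacent samples and
lags (m+1)..2m evaluated per level, with m = 16 points per octave by
default (the community standard). Normalization is symmetric —
G(tau) = mean(I_t I_{t+tau}) / (mean(I_t) mean(I_{t+tau})) − 1 over the
overlapping segments — which reduces drift bias. `autocorrelate_direct()`
is the brute-force reference evaluated at every integer lag; the test suite
holds the two routes equal to 1e-10 on randomized traces.

Two facts about finite traces matter for interpretation:

* **Amplitude.** For a Gaussian detection profile the amplitude-relevant
  spot area is pi w0^2: G(0) = 1 / (C pi w0^2) for particle density C. The
  *calibration* area printed for confocal spots, `pi w0^2 / 2` (0.071 um^2
  at 250 nm FWHM, matching the 0.06–0.07 um^2 usually quoted), is a
  different convention; `spot_calibration()` reports the latter, the
  correlator tests use the former.
* **Baseline bias.** Estimating the mean from the trace itself biases G by
  roughly −2·integral(G)/T. At T = 2 s and tau_D ≈ 11 ms this is a ~−0.01
  pedestal — enough to compress the fitted decay (raising apparent D by
  tens of percent and the anomalous exponent by ~0.1–0.3) if ignored.
  `fcs_fit(offset = TRUE)` adds a free additive baseline G_inf that
  absorbs it; with the offset the free-mode fit recovers
  tau_D = w0^2 / (4 D) essentially exactly. The offset is off by default so
  the plain analytic law is fitted; simulation-scale analyses in this
  package switch it on.

## FCS model fitting

`model_g()` is the standard 2D law
G(tau) = G0 [1 + T/(1−T) e^(−tau/tau_T)] Σ f_i (1 + (tau/tau_D,i)^alpha)^(−1);
the names ("2D", "triplet", "one-component") pin the model family and this
functional form is the one the field's fitting software uses. `fcs_fit()`
runs bounded Levenberg–Marquardt with a deterministic three-point
multi-start (amplitude-based, decay-midpoint, perturbed); non-convergence
is flagged, never silently defaulted. Weights are 1/sem^2 when the curve
carries uncertainties (e.g. from `average_curves()`), else uniform.
Bootstrap uncertainties re-correlate random contiguous half-length
sub-segments of the source trace and refit, 10 rounds by default —
segment-level resampling was chosen because residual resampling would
ignore the strong lag-to-lag correlation of FCS noise. Triplet kinetics
vary with fluorophore and excitation power, so no default triplet values
are assumed; when the triplet term is enabled its correlation time is
bounded to the photophysically plausible 1-100 us window.

`transit_to_D()` converts transit times by D = w0^2 / (4 tau_D) and
requires an explicit `spot_calibration()` — there is deliberately no
default spot. `counts_per_molecule()` is the intensive brightness
cpm = mean intensity × G0.

## Scanning FCS

A carpet is a pixels × scan-cycles matrix; each pixel is treated as sampled
once per cycle at the line frequency (intra-line dwell timing is not
modelled — per-pixel autocorrelation at the line frequency is what the
analysis consumes). The canonical order is fixed and asserted: crop the
first seconds (default 10 s), bleach-correct (default 18 s window), then
correlate and fit each pixel with the one-component 2D model. Bleach
correction computes a per-pixel moving-average trend and corrects
multiplicatively, I'(t) = I(t)·mean(I)/trend(t), then rescales to restore
the global mean exactly; the multiplicative form alone preserves the mean
only approximately, and the exact contract (stationary mean, mean
preservation to 1e-9) is what the tests pin down. Pixels whose trend
reaches zero are flagged and excluded; more than 50% failing pixels fails
the carpet. Fitted transit times and cpm values are pooled for the
population statistics below.

## Transit-time statistics

Pooled transit times are summarised by a log-normal location mu — through
the median e^mu — and width sigma. The primary estimates are raw-sample
maximum likelihood: closed form for the single model; for the two-component
mixture, expectation-maximization on log t with a deterministic multi-start
(a two-means split of log t plus two quantile-perturbed restarts) and a
sigma floor of 1e-3 (log scale) against degenerate spikes, flagged when
active. Components are always ordered median-descending: C1 slow, C2 fast.
Model choice is plain lower-BIC (k ln n − 2 ln L, k = 2 or 5) with the
margin delta-BIC exposed so users can impose a threshold; none is imposed
here because the selection rule is stated without one. The three
histogram views (linear, logarithmic, cumulative) and their least-squares
log-normal fits are retained as `histogram_modes()` diagnostics only:
fitting binned data is statistically inferior to the raw-sample MLE, and
how the three binned fits would be merged into one estimate is not
specified anywhere — so the package does not guess. Reported uncertainties
are per-dataset; aggregation across biological replicates is left to the
user.

The generators in `generate_transit_samples()` default to the scales
reported for labelled lipids in live cell membranes — medians of 21 ms
(free phospholipid), 42/25 ms (slow/fast sphingomyelin components) and
15/9 ms (cholesterol components) are the recovery targets in the tests,
at n = 10^4 within 10%.

## Partitioning (%Lo)

`extract_crossings()` samples a line profile across a vesicle equator
(opposite sides, cancelling polarization artifacts), finds one membrane
peak per half, subtracts the median of the off-membrane profile as
background (toggleable to raw peaks; whether source intensities were peak
or integrated is unstated, so peak is the default and integrated is
available), and labels the crossings Lo/Ld from a reference channel
marking the disordered phase. `percent_lo()` is
%Lo = 100 I_Lo / (I_Lo + I_Ld), with ordered preference above 50%. At
exactly 50% the preference is reported as "none" rather than forcing a
side. Lines that miss the vesicle (peaks not exceeding background by
4 robust standard deviations) raise an error.

## Synthetic data and what passing tests show

Every generator is seeded and carries a `ground_truth_record` sufficient to
regenerate its output bit-identically. The synthetic carpet evaluates the
detector at spot centres spaced along a line each scan cycle; bleaching is
injected multiplicatively at the detection stage so `bleach_correct()` is
tested in isolation from the diffusion physics. The vesicle images are
rings with two angular intensity halves, a Gaussian radial cross-section
standing in for the point spread, and optional additive noise.

The generators emulate the statistical structure the pipeline consumes —
Brownian/trap/hop motion, Gaussian detection, log-normal transit pools,
two-phase rims. They do not emulate detector afterpulsing or dead time,
membrane topography, leaflet asymmetry, or probe photophysics beyond the
optional exponential bleach. Recovery of ground truth here therefore
validates the estimators, not the biology: real membranes can and do
violate the generative assumptions.

## Problem sizes

The test suite and the acceptance script run simulations at the study's
parameters with durations of 2-5 s per run (several independent seeds pooled
per estimate), 10-s reduced-geometry carpets (16 pixels), and n = 10^4 for
mixture recovery — sizes chosen so a full check runs on a laptop in
minutes while keeping every estimate's sampling error well inside the
asserted tolerances. The acceptance criteria derive from the simulation
study's own reproducible surface: input-D recovery under free diffusion,
suppression of apparent D under trapping and hopping, the subdiffusive
anomalous-exponent band (0.65–1), the %Lo decision boundary, and the
statistical property suite.

## Known limitations

* The trapped-mode correlation decays *faster* than 1/tau at long lags
  (the immobile fraction's correlation dies exponentially with the
  trap-exchange time), so its anomalous fit can sit slightly above 1 —
  compressed rather than stretched — even though its apparent D is
  halved. Hop mode shows the classic subdiffusive alpha < 1. Both stay
  above the 0.65 lower bound.
* No 3D diffusion, no photophysics inside the simulator (blinking,
  bleaching of simulated particles), no leaflet-resolved kinetics, no
  cross-correlation, no 3+ component mixtures, no automated vesicle
  segmentation.
* The per-pixel bootstrap resamples curve segments; whether the original
  protocol bootstrapped segments or residuals is not stated, and the
  choice is labelled, not hidden.
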