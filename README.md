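# lipidfcs

Simulation and fluctuation analysis of nanoscale lipid diffusion in
membranes, for membrane biophysicists working with fluorescence correlation
spectroscopy (FCS).

Lipids in cell membranes rarely diffuse freely: transient binding
("trapping") and cytoskeleton-anchored meshworks ("hop diffusion") hinder
their motion at scales below the diffraction limit. FCS reads this out
through the autocorrelation of fluorescence fluctuations in a small
observation spot,

    G(tau) = <dI(t) dI(t+tau)> / <I>^2 ,

fitted with the two-dimensional diffusion law

    G(tau) = G0 [1 + T/(1-T) e^(-tau/tau_T)] * sum_i f_i (1 + (tau/tau_D,i)^alpha)^(-1) ,

where `G0 = 1/N` is the inverse mean spot occupancy, `tau_D` the transit
time (converted to a diffusion coefficient by `D = w0^2 / (4 tau_D)` with
the calibrated 1/e^2 spot radius `w0 = FWHM / sqrt(2 ln 2)`), `alpha` the
anomalous exponent (below 1 for subdiffusion), and the bracket an optional
triplet term. The package provides:

* **Monte Carlo simulator** (`sim_config()`, `simulate_diffusion()`):
  free, trapped (two-state Markov immobilisation), and hop diffusion on a
  Voronoi meshwork, probed by a Gaussian spot; Rcpp core, bit-reproducible
  from a seed.
* **Correlators** (`autocorrelate()`, `autocorrelate_direct()`,
  `average_curves()`): multi-tau scheme plus a brute-force reference.
* **Model fitting** (`fcs_fit()`, `model_g()`, `spot_calibration()`,
  `transit_to_D()`, `counts_per_molecule()`): bounded Levenberg-Marquardt
  with multi-start, bootstrap uncertainties, brightness analysis.
* **Scanning FCS** (`sfcs_carpet()`, `crop_initial()`, `bleach_correct()`,
  `analyze_carpet()`): line-scan carpets, photobleaching correction,
  per-pixel fitting, pooled transit times.
* **Transit-time statistics** (`transit_fit()`, `select_model_bic()`,
  `histogram_modes()`): single/double log-normal maximum likelihood with
  BIC model selection; component medians reported as `e^mu`.
* **Partitioning** (`extract_crossings()`, `percent_lo()`): liquid-ordered
  phase preference, `%Lo = 100 I_Lo / (I_Lo + I_Ld)`, from line profiles
  across two-phase vesicle images.
* **Synthetic data** (`generate_transit_samples()`,
  `generate_two_phase_vesicle()`, `generate_carpet()`): seeded generators
  with ground-truth records, and `run_pipeline()` to chain everything.

## Worked example

Simulate hop diffusion at the default study conditions (350 particles,
1 um^2/s microscopic diffusion, 110 nm mesh, p_hop = 0.05; 5 s per run,
three independent runs averaged), correlate, and fit:

```r
library(lipidfcs)

cal <- spot_calibration(fwhm = 250)
cal
#> Spot calibration: FWHM 250.0 nm, w0 212.3 nm, effective area 0.0708 um^2

curves <- lapply(1:3, function(s) {
  cfg <- sim_config(mode = "hop", duration = 5, seed = s)
  autocorrelate(simulate_diffusion(cfg))
})
fit <- fcs_fit(average_curves(curves), anomalous = TRUE, offset = TRUE,
               weights = "none", calibration = cal)
fit
#> 2D FCS fit (1 component, anomalous)
#>        G0    tau_D1     alpha     G_inf
#>  0.189278  0.014366  1.004163 -0.001962
#>   D = 0.7846 um^2/s
#>   cpm = 0.5141
```

The fitted apparent diffusion coefficient falls below the 1 um^2/s input:
the meshwork hinders transport, exactly how hop diffusion manifests in an
FCS experiment (a free-mode run instead returns D ≈ 1). Each run takes a
few minutes; the anomalous exponent of individual hindered runs scatters
around and below 1, dropping towards ~0.8 on well-averaged curves.

Transit-time population statistics with model selection:

```r
x <- generate_transit_samples(10000, "double", mu = log(c(42, 25)),
                              sigma = c(0.3, 0.3), B = 0.5, seed = 2)
transit_fit(x, model = "auto")
#> Double log-normal transit-time fit (n = 10000)
#>   C1 (slow): e^mu = 41.9 ms (sigma = 0.306), fraction B = 0.478
#>   C2 (fast): e^mu = 25.3 ms (sigma = 0.309), fraction 1-B = 0.522
#>   logLik = -39658.17, BIC = 79362.40  (selected by BIC; delta BIC single-double = 41.09)
```

Both generating medians (42 and 25 ms) and the mixture weight are
recovered, and the BIC margin of 41 decisively rejects the single
log-normal.

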