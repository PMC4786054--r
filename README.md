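# ptccd — simulation and measurement-error models for phosphor-taper-CCD X-ray area detectors

Detectors that couple a scintillating phosphor through a demagnifying
fibre-optic taper (FOT) to a CCD are the workhorse integrating detectors of
macromolecular crystallography. They are not photon counters: every stage of
the detection chain — phosphor absorption, scintillation amplification,
optical transmission, photoelectron conversion, read-out and digitization —
adds variance, and the point spread plus the software distortion correction
correlate neighbouring pixels. Integration software that assumes each pixel
is an independent Poisson counter therefore underestimates the random error
of Bragg-spot intensities, mildly for summation integration and severely for
profile fitting.

`ptccd` is for detector and integration-methods developers who want to
quantify that gap. It provides:

* a stochastic, event-level **forward simulator** of a 1024x1024 p-t-CCD
  module (phosphor, taper with radial cubic distortion, CCD with dark
  current, read noise, ADC bias and 16-bit clipping), plus the full image
  correction chain (dark, area-scaled flat field, distortion correction by
  polygon-overlap reapportioning);
* the closed-form **cascaded-gain noise algebra**: for a bias-corrected
  region sum `p` over `N` raw pixels,

  ```
  sigma^2(p) = gamma * G * p + N * psi,
  gamma = 1 + (sigma_g/g)^2 + (1/t - 1)/g,      psi = (g_ADC sigma_r)^2 + 1/12,
  DQE(n, N) = q_a / (gamma + N psi / (G^2 q_a n))
  ```

  with `G` the gain per absorbed and `G' = q_a G` per incident X-ray;
* MOSFLM-style **summation and profile-fitting integration** with three
  error models (independent-Poisson, cascade, and generalized least squares
  with an empirical pixel variance-covariance matrix), replicate
  spot-ensemble drivers, and a tabular calibration workflow that recovers
  `gamma`, `G` and `N psi` for a real detector from counting, dark-frame and
  beam-monitored intensity series.

## Worked example

The reference detector (12 keV, normal incidence, quantum absorption 0.85,
scintillation gain 281.5 +/- 163.3 photons, transmission 0.01715,
0.2 ADU/e-, 10 e- read noise):

```r
library(ptccd)
b <- noise_budget(cascade_params())
b
#> Detector noise budget
#>   cascade factor gamma : 1.5401
#>   pixel factor psi     : 4.0833 ADU^2/pixel
#>   gain G  (absorbed)   : 0.9655 ADU/photon
#>   gain G' (incident)   : 0.8207 ADU/photon
```

The cascade factor 1.54 says the detector's signal variance is 54% above
Poisson counting; the DQE of a 14x14-pixel region rises from 0.24 for a
500-photon spot towards the large-flux limit `q_a/gamma = 0.552`:

```r
round(dqe(c(5e2, 1e4, 1e8), 14^2, b), 3)
#> [1] 0.239 0.518 0.552
```

A replicate ensemble of simulated raw spot images (Gaussian spot of Poisson
mean 1e4 photons on a 20 X-ray/pixel background, integrated with a
23/23/5/4/11 measurement box):

```r
spec <- ensemble_spec(n_replicates = 300, zone = "A", seed = 42)
e <- run_spot_ensemble(spec, detector_config(), pipeline = "raw")
summary(e)
#> spot ensemble (raw pipeline, zone A, n = 300)
#>   mean(I_S) [ADU]              8219.5 (8.1)
#>   var(I_S) [ADU^2]            19806.4 (1619.9)
#>   mean Poisson est.           11882.3 (7.6)
#>   mean cascade est.           19128.8 (11.7)
#>   mean(I_P) [ADU]              8205.3 (7.0)
#>   var(I_P) [ADU^2]            14610.8 (1195.0)
#>   mean diag. prof. est.        6703.8 (27.5)
#>   var/mean-est ratio             2.18 (0.18)
```

Both integration methods recover the expected intensity
(`1e4 * G' = 8207 ADU`). The independent-Poisson estimate (~11.9e3 ADU^2)
falls well short of the observed scatter of the summation intensities
(~19e3 ADU^2), while the cascade estimator tracks it; the diagonal-weight
profile-fit estimate underestimates its observed scatter roughly two-fold on
raw images (worse still on distortion-corrected ones), which is what
covariance-aware (GLS) weighting repairs. For a real detector, the same
inversion that the simulator validates turns printed measurements into a
cascade factor:

```r
round(estimate_gamma(29608, 11926, 5454, 1.44), 2)   # observed var, signal, N*psi, G
#> [1] 1.41
```

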