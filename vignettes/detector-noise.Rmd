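---
title: "Measurement error in phosphor-taper-CCD diffraction images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error in phosphor-taper-CCD diffraction images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptccd)
```

## The problem

X-ray area detectors built from a scintillating phosphor, a demagnifying
fibre-optic taper (FOT) and a CCD are integrating devices, not photon
counters. Between an incident Bragg-spot photon and the integer ADU values a
crystallographer integrates lie several stochastic gain and loss stages, a
point spread that correlates neighbouring pixels, per-pixel read-out and
digitization noise, and software corrections (dark, flat field, geometric
distortion) that reshape both the signal and its covariance. Error models
that treat every pixel as an independent Poisson counter therefore
underestimate the true random error of integrated intensities — mildly for
summation integration, severely for profile fitting.

`ptccd` provides three connected things:

1. a stochastic forward simulator of such a detector, event by event;
2. the closed-form cascaded-gain noise algebra that predicts its response;
3. integration routines (summation and profile fitting) with error
   estimators that either assume independent Poisson pixels, apply the
   cascade model, or use an explicit pixel variance-covariance matrix —
   plus ensemble drivers that compare all of them against the observed
   scatter.

## The detection cascade and its algebra

A detection event passes through: Poisson arrival of X-rays; binomial
interaction with the phosphor (quantum absorption $\bar q_a$); emission of
light photons with scintillation-spectrum mean $\bar g$ and SD $\sigma_g$;
binomial survival of each light photon through the optical chain with
probability $\bar t$ (taper acceptance x transmittance x stub coupling x CCD
quantum efficiency); and one photoelectron per detected photon
($\bar e = 1$, since the 545 nm emission cannot create more than one
electron-hole pair). Read-out adds Gaussian noise of $\sigma_r$ electrons
per pixel and the ADC applies a gain $g_{ADC}$ (ADU per electron), rounds,
and adds a constant bias.

Summing the per-stage relative variances, each normalized by the input
quanta of its stage, and folding constants gives the **cascade factor**

$$\gamma = 1 + \left(\frac{\sigma_g}{\bar g}\right)^2 +
  \frac{1/\bar t - 1}{\bar g},$$

the multiplicative excess of the signal variance over Poisson counting, and
the **pixel factor**

$$\psi = (g_{ADC}\,\sigma_r)^2 + \tfrac{1}{12}\ \mathrm{ADU^2/pixel},$$

the additive per-pixel noise (the $1/12$ is the pseudo-quantization model —
digitization error uniform over 1 ADU — valid because the read noise spans
2 ADU here). The gains are $G = \bar g\,\bar t\,\bar e\,g_{ADC}$ per
*absorbed* photon and $G' = \bar q_a G$ per *incident* photon; $G'$ is what
a counting experiment measures, $G$ is what error estimation from pixel
values needs. A bias-corrected region sum $p$ over $N$ raw pixels then has

$$\sigma^2(p) = \gamma\,G\,p + N\psi,$$

and the zero-frequency detective quantum efficiency follows as

$$\mathrm{DQE}(\bar n, N) =
  \frac{\bar q_a}{\gamma + N\psi/(G^2 \bar q_a \bar n)}
  \ \xrightarrow{\ \bar n \to \infty\ }\ \frac{\bar q_a}{\gamma}.$$

The default parameters describe a realistic 12 keV, normal-incidence
detector: $\bar q_a = 0.85$, $\bar g = 281.5$, $\sigma_g = 163.3$ photons,
$\bar t = 0.50 \times 0.14 \times 0.70 \times 0.35 = 0.01715$,
$g_{ADC} = 0.2$ ADU/e-, $\sigma_r = 10$ e-, giving $\gamma = 1.54$,
$\psi = 4.083$ ADU$^2$, $G = 0.966$, $G' = 0.821$:

```{r budget}
noise_budget(cascade_params())
```

## The forward simulator

`simulate_image()` turns a table of X-ray impact positions on the 1024 x
1024, 73 um-pitch detector face into a 16-bit raw image on the 1024 x 1024,
30 um-pitch CCD: phosphor absorption and scintillation, a point-spread
displacement per light photon, binomial optical survival, the taper's
2.7:1 radially distorting mapping, pixel binning, dark current
(0.01 e-/px/s), read noise, ADC rounding (half-to-even), a 500 ADU bias and
a 65535 clip.

Three model components are not pinned down by first principles and were
fixed once, as follows:

* **Scintillation spectrum.** A gamma distribution with the configured mean
  and SD, rounded to integers. Every statistic the package predicts depends
  on this distribution only through its first two moments, so a two-moment
  model is sufficient; the specific family only matters for far-tail
  behaviour that nothing here measures.
* **Point spread.** A radial mixture of a Gaussian core (24%,
  $\sigma$ = 15.5 um) and an exponential tail (76%, scale 30 um). Phosphor
  point spreads are bounded by FWHM < 40 um and FW10%M < 100 um, and the
  *full-system* point spread (phosphor plus optical chain) is slightly wider
  than the phosphor alone, so the mixture is calibrated to sit just inside
  those bounds: FWHM 38 um, FW10%M 95 um (`psf_widths()` verifies this
  numerically at construction time in the test suite). A longer-tailed
  mixture with the same two widths was rejected because its tail would leak
  a measurable fraction of a spot's light out of any realistic peak region,
  which would contradict the exact intensity recovery that summation
  integration achieves on these ensembles; the chosen mixture's leakage is
  negligible at the spot sizes used (the ensemble tests assert the recovery
  directly).
* **Taper distortion.** A radial cubic
  $r_{ccd} = (r_{face}/2.7)(1 + k_2 r_{face}^2)$ (pincushion), with $k_2$
  set so the cubic term displaces the face corner by 3 corrected pixels.
  Real tapers are messier (chicken wire, shear); only the continuous radial
  component is modelled, so the *specific spatial pattern* of corrected-image
  covariance is illustrative, while its mechanism (non-commensurate grid
  reapportioning) is faithful. Bijectivity is checked at construction.

Two exact distributional identities speed the ensemble engine without
changing the model: absorbed X-rays of a Poisson flux are generated directly
(Poisson thinning), and point-spread displacements are only drawn for light
photons that survive the optics (binomial thinning commutes with i.i.d.
displacement). The staged functions `phosphor_stage()`, `taper_stage()` and
`ccd_expose()` realise the same chain event by event and are tested for
moment agreement.

## Correction chain

`correct_image()` applies, in order: dark subtraction (a 200-image average
dark removes the bias and dark signal while adding only
$\sigma_r/\sqrt{200}$ of noise); flat-field division, where the flat is an
average of dark-corrected flood exposures scaled by each CCD pixel's
effective collection area at the face (the distortion is non-area
preserving, so even a uniform response shows a density gradient) and
normalized to mean 1; and distortion correction, which maps each CCD
pixel's corners back along the taper to a face quadrilateral and
reapportions its value onto the orthogonal 73 um grid in proportion to
clipped-polygon overlap areas (Sutherland-Hodgman clipping of convex quads
against axis-aligned cells, shoelace areas; quads are convex for any
monotone radial distortion, so no general clipping library is needed).
Conservation of reapportioned signal is exact up to pixels that leave the
target window, which are counted and reported. A configurable pedestal
(default 10 ADU) is re-added for 16-bit storage.

Because the simulated response is inherently uniform, flat fielding here
*introduces* a small position-dependent systematic error (the finite-count
imprecision of the flood average) rather than removing a larger one — the
corrected-image ensembles deliberately carry this signature of real
pipelines.

## Integration and error models

`measurement_box()` builds the classic box: odd side lengths NX, NY; rim
widths NRX, NRY separating background from peak; and a corner cut NC under
which pixels with $|dx| + |dy| > NC$ are moved from the peak to the
background. Box parameters are quoted in face-grid (corrected-image) pixels;
`convert_box_params()` rescales them by the pixel-pitch ratio
$73/(2.7 \times 30)$ — side lengths to the nearest odd integer — so the same
physical region is integrated on raw images. Two conventions here were
genuinely open and were fixed by requiring internal consistency of the error
algebra with the integrated intensities the box definitions produce: corner
pixels are *background* (not discarded), and the cut is strict
($> NC$, so the reference 23/23/5/4/11 box has M = 183 peak and N = 346
background pixels).

The background plane is an unweighted least-squares fit to the background
pixels; by mm symmetry of the box its constant equals the background mean
and the summation intensity reduces to
$I_S = \sum_{peak}\rho_i - (M/N)\sum_{bg}\rho_i$. Three variance estimates
are offered:

* **Independent-Poisson** (`variance_poisson_mosflm()`):
  $G[I_S + I_{bg}(1 + M/N)]$.
* **Cascade** (`variance_cascade()`): the region-sum law applied to the peak
  and background totals,
  $[\gamma G P_{peak} + M_{raw}\psi] + (M/N)^2[\gamma G P_{bg} + N_{raw}\psi]$.
  For corrected images the raw-pixel counts behind the regions are computed
  exactly from the distortion map as $\sum_i w_i^2$ over apportionment
  fractions ([effective_raw_pixels()]); approximating them by the
  corrected-box counts is the documented fallback and slightly overestimates.
* **Profile fitting** (`profile_fit()`): the reference profile (mean of 20
  background-corrected boxes, integer-rounded) and a background plane are
  fitted jointly by least squares. With diagonal independent-Poisson weights
  the variance is the *residual-scaled* WLS covariance
  $s^2[(X^TWX)^{-1}]_{KK}(\sum\phi)^2$ — the "quality of fit" error. This
  choice matters: because correlated pixels are smoothed, the apparent fit
  quality improves while the true scatter does not, which is exactly the
  underestimation pathology the ensemble drivers quantify; an unscaled
  Poisson propagation could not reproduce the characteristic drop of the
  estimate on distortion-corrected images. With a full covariance matrix
  (`empirical_pixel_covariance()`, sample covariances truncated beyond lag
  7 in X and Y, eigenvalue-clipped if a small ensemble leaves it non-PSD)
  the fit becomes GLS and the variance is the unscaled
  $[(X^T M_f^{-1} X)^{-1}]_{KK}(\sum\phi)^2$.

## Ensemble studies and the calibration workflow

`run_spot_ensemble()` reproduces the replicate-spot study design: a
two-dimensional Gaussian spot (default $\sigma$ = 80 um, chosen so that
>99.9% of spot light falls inside the peak region of both box flavours)
with Poisson-distributed total count (mean $10^4$) on a uniform background
of 20 X-rays per face pixel, in zone A (face pixel 306, 306) or zone B
(shifted six pixels in X and Y, sampling a different grid registration).
Only the sub-region around the measurement box is simulated; totals-based
checks against occasional larger windows are part of the test suite.
`summary()` reports the mean and observed variance of $I_S$ and $I_P$, the
ensemble means of every estimator, and the observed-to-estimated profile
variance ratio, each with standard errors.

For real detectors none of the stage parameters are directly observable, so
the package includes the tabular workflow that recovers them:
`gain_from_counting()` (G' as a through-origin slope of integrated intensity
against simultaneous scintillation-counter photon counts, rescaled by a
two-spot relative-intensity factor, with the SE combining both fit stages),
`pixel_noise_from_darks()` ($N\psi$ as the variance of the box sum over
no-beam exposures), `trend_residual_variance()` (response variance as the
pooled residual variance about per-section, monitor-proportional trend fits
— sections demarcated by abrupt beam changes such as top-up injections,
pooled unweighted), and `estimate_gamma()` to invert the region-sum law.
`make_response_fixture()` generates synthetic series with a known
$(\gamma, G, N\psi)$ and a drifting, sectioned trend for end-to-end recovery
tests; it emulates the tabular data such an experiment produces, not the
beamline geometry that produced it.

## Problem sizes, tolerances and numerical choices

* Ensemble sizes: the bundled acceptance runs use $10^4$ raw and
  2 x $10^3$ corrected replicates (the study design scales to $10^5$);
  statistical tests use 3 combined standard errors at the size actually
  run, computed from the per-replicate scatter.
* The GLS-recovery check runs on a reduced (11 x 11 face-unit) box: the
  inverse of a p-dimensional empirical covariance estimated from n samples
  is biased upward by O(p/n), so the full 529-pixel box would need far
  larger ensembles than a test suite should carry; p/n is kept near 3%.
* Distortion-map inversion uses Newton iterations on the radial cubic
  (machine precision in < 12 steps for monotone mappings); polygon areas
  use the shoelace formula; degenerate quads raise errors rather than
  warnings.
* ADC rounding is round-half-to-even; the quantization variance then follows
  the 1/12 pseudo-quantization model asserted against a Monte-Carlo oracle.
* All stochastic entry points take explicit seeds; ensembles record theirs,
  and identical seeds reproduce bit-identical images.

## What passing tests do and do not show

The simulator emulates: cascade statistics with realistic moments, a
calibrated point spread, continuous radial distortion, uniform response,
dark/flat/distortion corrections, and the ensemble designs above. It does
not emulate: energy or obliquity dependence of the response, polychromatic
beams, zingers, pixel bleeding at overload, chicken-wire or shear taper
defects, reflective phosphor backing, or sub-pixel response granularity.
Consequently, agreement of the error estimators with observed ensemble
scatter here validates the *model structure* (cascade + pixel noise +
covariance), while the absolute parameter values of any physical detector —
and the exact spatial pattern of its corrected-image covariance — must be
calibrated per device with the workflow above. The profile-fit
underestimation ratios in particular are sensitive to the true point-spread
width and the true distortion field; on this simulator they are reproduced
at the tens-of-percent level, and their orderings (diagonal estimate <
observed variance; GLS estimate ~ observed variance) are exact properties
that the test suite asserts.
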