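#' Stochastic stage parameters of the detection cascade
#'
#' Bundles the per-stage parameters of a phosphor-taper-CCD detection chain:
#' phosphor quantum absorption, scintillation gain (mean and spread), overall
#' optical transmission times CCD quantum efficiency, photoelectron yield,
#' ADC gain, read-out noise and the digitization-noise variance.
#'
#' Defaults describe the reference simulated detector: a Gd2O2S:Tb phosphor
#' viewed in transmission at 12 keV through a 2.7:1 fibre-optic taper onto a
#' CCD read at 0.2 ADU per electron with 10 e- r.m.s. read noise.
#'
#' @param q_abs probability that an incident X-ray interacts with the
#'   phosphor (quantum absorption).
#' @param gain_mean mean number of light photons emitted per absorbed X-ray
#'   (scintillation gain).
#' @param gain_sd standard deviation of the scintillation gain, photons.
#' @param transmission probability that an emitted light photon is transmitted
#'   through the optical chain *and* detected by the CCD. The default is the
#'   product 0.50 (taper acceptance) x 0.14 (taper transmittance) x 0.70
#'   (taper-to-stub acceptance) x 0.35 (CCD quantum efficiency).
#' @param e_yield photoelectrons per detected light photon. Monoenergetic
#'   545 nm emission can create at most one electron-hole pair, so this is 1;
#'   it is kept as a parameter so the variance algebra stays general.
#' @param g_adc ADC gain in ADU per electron.
#' @param read_noise_e read-out noise, electrons r.m.s. per pixel.
#' @param digitization_var_adu2 variance of the quantization error per pixel,
#'   ADU^2. Defaults to 1/12 (pseudo-quantization model: error uniform over
#'   1 ADU, valid here because the read noise spans 2 ADU > 1 ADU).
#' @return an object of class `cascade_params`.
#' @seealso [noise_budget()], [detector_config()]
#' @export
#' @examples
#' p <- cascade_params()
#' noise_budget(p)
cascade_params <- function(q_abs = 0.85,
                           gain_mean = 281.5,
                           gain_sd = 163.3,
                           transmission = 0.50 * 0.14 * 0.70 * 0.35,
                           e_yield = 1,
                           g_adc = 0.2,
                           read_noise_e = 10,
                           digitization_var_adu2 = 1 / 12) {
  stopifnot(is.numeric(q_abs), length(q_abs) == 1L)
  if (q_abs < 0 || q_abs > 1)
    stop("'q_abs' must lie in [0, 1]", call. = FALSE)
  if (transmission <= 0 || transmission > 1)
    stop("'transmission' must lie in (0, 1]", call. = FALSE)
  if (gain_mean <= 0) stop("'gain_mean' must be positive", call. = FALSE)
  if (gain_sd < 0) stop("'gain_sd' must be non-negative", call. = FALSE)
  if (g_adc <= 0) stop("'g_adc' must be positive", call. = FALSE)
  if (read_noise_e < 0) stop("'read_noise_e' must be non-negative", call. = FALSE)
  if (digitization_var_adu2 < 0)
    stop("'digitization_var_adu2' must be non-negative", call. = FALSE)
  structure(
    list(q_abs = q_abs, gain_mean = gain_mean, gain_sd = gain_sd,
         transmission = transmission, e_yield = e_yield, g_adc = g_adc,
         read_noise_e = read_noise_e,
         digitization_var_adu2 = digitization_var_adu2),
    class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Cascade stage parameters (p-t-CCD detection chain)\n")
  cat(sprintf("  quantum absorption q_abs : %.4g\n", x$q_abs))
  cat(sprintf("  scintillation gain       : %.4g +/- %.4g photons\n",
              x$gain_mean, x$gain_sd))
  cat(sprintf("  optical transmission     : %.4g\n", x$transmission))
  cat(sprintf("  ADC gain                 : %.4g ADU/e-\n", x$g_adc))
  cat(sprintf("  read noise               : %.4g e- r.m.s.\n", x$read_noise_e))
  invisible(x)
}

#' Derive the noise budget of a detection cascade
#'
#' Folds the per-stage relative variances of the cascade into the cascade
#' factor gamma and the per-pixel additive noise into the pixel factor psi,
#' and computes the apparent gains per absorbed (`G`) and per incident (`G'`)
#' X-ray photon.
#'
#' The cascade chain contributes, per absorbed photon,
#' \deqn{\gamma = 1 + (\sigma_g/\bar g)^2 + (1/\bar t - 1)/\bar g,}
#' i.e. the Poisson term, the Swank (scintillation-spread) term and the
#' binomial transmission term; the unit-yield photoelectron stage adds no
#' variance. The pixel factor is
#' \deqn{\psi = (g_{ADC}\,\sigma_r)^2 + \mathrm{Var}(d)}
#' in ADU^2 per raw pixel (read-out plus digitization noise).
#'
#' @param params a [cascade_params()] object.
#' @return an object of class `noise_budget`: list with `gamma`, `psi`
#'   (ADU^2/pixel), `gain_absorbed` (G, ADU per interacting X-ray),
#'   `gain_incident` (G', ADU per incident X-ray), and the originating
#'   `params`.
#' @export
#' @examples
#' b <- noise_budget(cascade_params())
#' round(b$gamma, 2)  # 1.54 for the reference detector
noise_budget <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  gamma <- 1 + (params$gain_sd / params$gain_mean)^2 +
    (1 / params$transmission - 1) / params$gain_mean
  psi <- (params$g_adc * params$read_noise_e)^2 + params$digitization_var_adu2
  G <- params$gain_mean * params$transmission * params$e_yield * params$g_adc
  structure(
    list(gamma = gamma, psi = psi,
         gain_absorbed = G, gain_incident = params$q_abs * G,
         params = params),
    class = "noise_budget")
}

#' @export
print.noise_budget <- function(x, ...) {
  cat("Detector noise budget\n")
  cat(sprintf("  cascade factor gamma : %.4f\n", x$gamma))
  cat(sprintf("  pixel factor psi     : %.4f ADU^2/pixel\n", x$psi))
  cat(sprintf("  gain G  (absorbed)   : %.4f ADU/photon\n", x$gain_absorbed))
  cat(sprintf("  gain G' (incident)   : %.4f ADU/photon\n", x$gain_incident))
  invisible(x)
}

#' Expected bias-corrected signal in ADU
#'
#' Expected value of the summed, bias-corrected pixel signal produced by a
#' mean number of incident X-rays: `n_incident_mean * G'`.
#'
#' @param n_incident_mean mean number of X-rays incident on the region.
#' @param params a [cascade_params()] object (or a [noise_budget()]).
#' @return expected signal in ADU.
#' @export
expected_signal_adu <- function(n_incident_mean, params) {
  if (any(n_incident_mean < 0))
    stop("'n_incident_mean' must be non-negative", call. = FALSE)
  b <- if (inherits(params, "noise_budget")) params else noise_budget(params)
  n_incident_mean * b$gain_incident
}

#' Cascade-model variance of a region sum
#'
#' Variance of a bias-corrected sum of pixel values, estimated from a single
#' observation of the signal:
#' \deqn{\sigma^2(p) = \gamma\,G\,p + N\,\psi}
#' where `p` is the observed (bias-subtracted) region sum in ADU and `N` the
#' number of raw-image pixels contributing read-out and digitization noise.
#'
#' Dividing signal and variance by `G` and `G^2` gives the count-unit form
#' `gamma * counts + N psi / G^2`; the two are the same relation viewed in
#' different units.
#'
#' @param signal_adu observed bias-corrected region sum, ADU (>= 0).
#' @param n_pixels number of contributing raw pixels (>= 1).
#' @param budget a [noise_budget()] object.
#' @return estimated variance in ADU^2.
#' @export
signal_variance_adu2 <- function(signal_adu, n_pixels, budget) {
  stopifnot(inherits(budget, "noise_budget"))
  if (any(signal_adu < 0))
    stop("'signal_adu' must be non-negative (bias-subtracted)", call. = FALSE)
  if (any(n_pixels < 1)) stop("'n_pixels' must be >= 1", call. = FALSE)
  budget$gamma * budget$gain_absorbed * signal_adu + n_pixels * budget$psi
}

#' Estimate the cascade factor from measured signal statistics
#'
#' Inverts the region-sum variance model: given an observed variance, the
#' signal it belongs to, the total pixel-noise contribution and the
#' absorbed-photon gain,
#' \deqn{\hat\gamma = (\sigma^2_{obs} - N\psi) / (G\,\bar s).}
#'
#' @param observed_variance observed variance of the region sum, ADU^2.
#' @param signal mean bias-corrected region sum, ADU (> 0).
#' @param pixel_noise_total total pixel-noise variance `N psi`, ADU^2.
#' @param gain_absorbed absorbed-photon gain G, ADU per interacting X-ray.
#' @return estimate of the cascade factor (unitless). A value of 0 (variance
#'   exactly at the noise floor) is returned with a warning.
#' @export
#' @examples
#' # printed real-detector example: 1.41
#' round(estimate_gamma(29608, 11926, 5454, 1.44), 2)
estimate_gamma <- function(observed_variance, signal, pixel_noise_total,
                           gain_absorbed) {
  if (signal <= 0) stop("'signal' must be positive", call. = FALSE)
  if (gain_absorbed <= 0) stop("'gain_absorbed' must be positive", call. = FALSE)
  if (observed_variance < pixel_noise_total)
    stop("observed variance lies below the pixel-noise floor; ",
         "non-physical input", call. = FALSE)
  g <- (observed_variance - pixel_noise_total) / (gain_absorbed * signal)
  if (g == 0)
    warning("observed variance equals the pixel-noise floor; ",
            "cascade variance is degenerate (gamma = 0)")
  g
}

#' Convert a per-incident-photon gain to a per-absorbed-photon gain
#'
#' `G = G' / q_abs`: the independently measurable gain counts all incident
#' photons, while error estimates from pixel values concern only photons that
#' actually interacted with the phosphor.
#'
#' @param g_incident gain per incident photon, ADU/photon.
#' @param q_abs phosphor quantum absorption, in (0, 1].
#' @return gain per absorbed photon, ADU/photon.
#' @export
#' @examples
#' round(gain_incident_to_absorbed(1.22, 0.85), 2)  # 1.44
gain_incident_to_absorbed <- function(g_incident, q_abs) {
  if (any(q_abs <= 0) || any(q_abs > 1))
    stop("'q_abs' must lie in (0, 1]", call. = FALSE)
  g_incident / q_abs
}

#' Zero-frequency detective quantum efficiency
#'
#' DQE is the squared output signal-to-noise ratio over the squared input
#' signal-to-noise ratio. With Poisson input (variance = mean) and the
#' cascade + pixel noise output model this reduces to
#' \deqn{\mathrm{DQE}(\bar n, N) =
#'   \frac{\bar q_a}{\gamma + N\psi / (G^2 \bar q_a \bar n)}.}
#' The phosphor quantum absorption bounds the DQE above and the cascade
#' factor sets the large-flux limit `q_abs / gamma`; pixel noise degrades
#' weak signals in proportion to the region size `N`.
#'
#' The closed form is verified against the Monte-Carlo simulator in the test
#' suite; both routes derive from the same signal/variance expressions.
#'
#' @param n_incident_mean mean number of incident X-rays (> 0); vectorized.
#' @param n_pixels number of pixels the signal is collected over (>= 1).
#' @param budget a [noise_budget()] object.
#' @param q_abs phosphor quantum absorption; defaults to the value in the
#'   budget's parameters.
#' @return DQE values in (0, q_abs].
#' @export
#' @examples
#' b <- noise_budget(cascade_params())
#' dqe(1e4, 10 * 10, b)
dqe <- function(n_incident_mean, n_pixels, budget,
                q_abs = budget$params$q_abs) {
  stopifnot(inherits(budget, "noise_budget"))
  if (any(n_incident_mean <= 0))
    stop("'n_incident_mean' must be positive", call. = FALSE)
  if (any(n_pixels < 1)) stop("'n_pixels' must be >= 1", call. = FALSE)
  q_abs / (budget$gamma +
             n_pixels * budget$psi /
               (budget$gain_absorbed^2 * q_abs * n_incident_mean))
}
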