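#' Generate X-ray impact positions for a Gaussian diffraction spot
#'
#' The number of X-rays is Poisson with the given mean; positions are i.i.d.
#' isotropic Gaussian about the spot centre on the detector face.
#'
#' @param center_um length-2 vector, spot centre on the face (um from the
#'   face corner).
#' @param sigma_um isotropic Gaussian spread of the spot, um (> 0).
#' @param mean_count mean number of X-ray photons in the spot (>= 0).
#' @param seed optional integer; when given, seeds the RNG first.
#' @return a `photon_table`: data frame with `x_um`, `y_um` and an
#'   `energy_keV` attribute.
#' @export
generate_spot_photons <- function(center_um, sigma_um, mean_count,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(center_um) == 2L, sigma_um > 0, mean_count >= 0)
  n <- stats::rpois(1L, mean_count)
  photon_table(center_um[1L] + stats::rnorm(n, 0, sigma_um),
               center_um[2L] + stats::rnorm(n, 0, sigma_um))
}

#' Generate a uniform X-ray flood over a face region
#'
#' Counts are i.i.d. Poisson per 73 um face pixel, with positions uniform
#' within each pixel.
#'
#' @param mean_per_pixel mean X-rays per face pixel (>= 0).
#' @param region list with integer vectors `x` and `y`: 1-based index ranges
#'   `c(first, last)` of face pixels covered.
#' @param face_pixel_um face pixel pitch, um.
#' @param seed optional integer seed.
#' @return a `photon_table`.
#' @export
generate_flood_photons <- function(mean_per_pixel, region,
                                   face_pixel_um = 73, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mean_per_pixel >= 0)
  xi <- region$x[1L]:region$x[2L]
  yi <- region$y[1L]:region$y[2L]
  counts <- stats::rpois(length(xi) * length(yi), mean_per_pixel)
  n <- sum(counts)
  if (n == 0L) return(photon_table(numeric(0), numeric(0)))
  px <- rep.int(rep(xi, times = length(yi)), counts)
  py <- rep.int(rep(yi, each = length(xi)), counts)
  photon_table((px - 1 + stats::runif(n)) * face_pixel_um,
               (py - 1 + stats::runif(n)) * face_pixel_um)
}

#' @rdname generate_spot_photons
#' @param x_um,y_um impact coordinates, um from the face corner.
#' @param energy_keV photon energy (monoenergetic).
#' @export
photon_table <- function(x_um, y_um, energy_keV = 12) {
  structure(data.frame(x_um = x_um, y_um = y_um),
            energy_keV = energy_keV,
            class = c("photon_table", "data.frame"))
}

#' Phosphor stage: absorption, scintillation gain and point spread
#'
#' Each incident X-ray interacts with probability `q_abs`; each absorbed
#' X-ray emits an integer number of light photons drawn from the
#' scintillation spectrum (a gamma distribution matched to the configured
#' mean and SD, rounded to integers); each light photon is displaced from the
#' impact point by an independent draw from the point-spread model.
#'
#' @param photons a [photon_table()] of incident X-rays.
#' @param params a [cascade_params()] (absorption and gain moments).
#' @param psf a [psf_model()].
#' @param seed optional integer seed.
#' @return list with `xy` (matrix of light-photon face positions, um),
#'   `n_absorbed`, and `photons_per_event` (emitted count per absorbed
#'   X-ray).
#' @export
phosphor_stage <- function(photons, params, psf = psf_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(params, "cascade_params"))
  n <- nrow(photons)
  n_abs <- stats::rbinom(1L, n, params$q_abs)
  if (n_abs == 0L)
    return(list(xy = matrix(numeric(0), 0L, 2L), n_absorbed = 0L,
                photons_per_event = integer(0)))
  # incident positions are i.i.d., so the absorbed subset is a simple sample
  idx <- if (n_abs == n) seq_len(n) else sample.int(n, n_abs)
  if (params$gain_sd > 0) {
    shape <- (params$gain_mean / params$gain_sd)^2
    k <- as.integer(round(stats::rgamma(n_abs, shape = shape,
                                        scale = params$gain_mean / shape)))
  } else {
    k <- rep.int(as.integer(round(params$gain_mean)), n_abs)
  }
  parent <- rep.int(idx, k)
  disp <- psf_sample(length(parent), psf)
  list(xy = cbind(photons$x_um[parent] + disp[, 1L],
                  photons$y_um[parent] + disp[, 2L]),
       n_absorbed = n_abs, photons_per_event = k)
}

#' Taper stage: optical transmission and geometric mapping to the CCD
#'
#' Each light photon independently survives the optical chain (taper
#' acceptance and transmittance, stub coupling, CCD quantum efficiency folded
#' into one binomial probability) and surviving photons are mapped from the
#' detector face to the CCD plane through the taper's demagnifying, radially
#' distorting geometry. Photons mapped outside the CCD are dropped and
#' counted.
#'
#' @param light output of [phosphor_stage()] (or any list with an `xy`
#'   position matrix in face um).
#' @param taper a [taper_model()].
#' @param transmission survival probability per light photon.
#' @param seed optional integer seed.
#' @return list with `xy` (CCD-plane positions of detected photons, um) and
#'   `n_dropped` (survivors mapped off the CCD).
#' @export
taper_stage <- function(light, taper, transmission, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(taper, "taper_model"),
            transmission > 0, transmission <= 1)
  n <- nrow(light$xy)
  keep <- stats::runif(n) < transmission
  ccd <- face_to_ccd(light$xy[keep, , drop = FALSE], taper)
  lim <- taper$n_ccd * taper$ccd_pixel_um
  inside <- ccd[, 1L] >= 0 & ccd[, 1L] < lim & ccd[, 2L] >= 0 & ccd[, 2L] < lim
  list(xy = ccd[inside, , drop = FALSE], n_dropped = sum(!inside))
}

#' CCD stage: charge accumulation, read-out and digitization
#'
#' Detected photons are binned into CCD pixels at unit photoelectron yield;
#' dark current accumulates as Poisson electrons over the exposure; Gaussian
#' read noise is added per pixel; the ADC applies the gain, rounds
#' half-to-even, adds the constant bias, and clips to the 16-bit range.
#'
#' @param ccd_photons output of [taper_stage()] (list with CCD-plane `xy`).
#' @param exposure_s exposure length, seconds (> 0).
#' @param config a [detector_config()].
#' @param window optional list with `x`, `y` integer ranges `c(first, last)`
#'   of CCD pixels: only this sub-raster is formed (default: full frame).
#' @param kind image kind flag: `"raw"`, `"dark"` or `"flood"`.
#' @param seed optional integer seed.
#' @return a `ptccd_image`: integer matrix (rows index X, columns Y) with
#'   attributes `kind`, `exposure_s`, `origin` (1-based full-grid index of
#'   `[1, 1]`), `pixel_um` and `seed`.
#' @export
ccd_expose <- function(ccd_photons, exposure_s, config, window = NULL,
                       kind = "raw", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "detector_config"), exposure_s > 0)
  tp <- config$taper
  if (is.null(window))
    window <- list(x = c(1L, tp$n_ccd), y = c(1L, tp$n_ccd))
  nx <- window$x[2L] - window$x[1L] + 1L
  ny <- window$y[2L] - window$y[1L] + 1L
  counts <- bin_positions(ccd_photons$xy, tp$ccd_pixel_um, window, nx, ny)
  out <- ccd_readout(counts, window, exposure_s, config, kind)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else seed
  out
}

# read-out chain shared by ccd_expose and the ensemble engine: dark current,
# read noise, ADC rounding (half-to-even), bias, 16-bit clip
ccd_readout <- function(counts, window, exposure_s, config, kind) {
  nx <- window$x[2L] - window$x[1L] + 1L
  ny <- window$y[2L] - window$y[1L] + 1L
  electrons <- counts * config$params$e_yield
  npx <- nx * ny
  dark_rate <- config$dark_e_per_px_s * exposure_s
  if (dark_rate > 0) electrons <- electrons + stats::rpois(npx, dark_rate)
  electrons <- electrons + stats::rnorm(npx, 0, config$params$read_noise_e)
  adu <- round(config$params$g_adc * electrons) + config$bias_adu
  adu <- pmin(pmax(adu, 0), 65535)
  structure(matrix(as.integer(adu), nx, ny),
            kind = kind, exposure_s = exposure_s,
            origin = c(window$x[1L], window$y[1L]),
            pixel_um = config$taper$ccd_pixel_um,
            seed = NA_integer_,
            class = "ptccd_image")
}

# bin continuous positions (um) into a pixel window; positions outside the
# window are discarded
bin_positions <- function(xy, pixel_um, window, nx, ny) {
  if (nrow(xy) == 0L) return(numeric(nx * ny))
  ix <- floor(xy[, 1L] / pixel_um) + 1 - (window$x[1L] - 1L)
  iy <- floor(xy[, 2L] / pixel_um) + 1 - (window$y[1L] - 1L)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  tabulate((ix[ok] - 1) + nx * (iy[ok] - 1) + 1, nbins = nx * ny)
}

#' Simulate a raw image from a table of incident X-ray positions
#'
#' Composition of the phosphor, taper and CCD stages. Deterministic given the
#' seed.
#'
#' @inheritParams ccd_expose
#' @param photons a [photon_table()] of incident X-rays on the detector face.
#' @return a raw `ptccd_image` (see [ccd_expose()]).
#' @export
#' @examples
#' cfg <- detector_config()
#' spot <- generate_spot_photons(c(22301.5, 22301.5), 80, 1000, seed = 1)
#' img <- simulate_image(spot, cfg, window = list(x = c(320, 332), y = c(320, 332)),
#'                       seed = 2)
simulate_image <- function(photons, config, exposure_s = 1, window = NULL,
                           kind = "raw", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "detector_config"))
  light <- phosphor_stage(photons, config$params, config$psf)
  ccd <- taper_stage(light, config$taper, config$params$transmission)
  ccd_expose(ccd, exposure_s, config, window = window, kind = kind)
}

#' @export
print.ptccd_image <- function(x, ...) {
  o <- attr(x, "origin")
  cat(sprintf("%s p-t-CCD image: %d x %d px (origin %d, %d), %g um pitch, %g s\n",
              attr(x, "kind"), nrow(x), ncol(x), o[1L], o[2L],
              attr(x, "pixel_um"), attr(x, "exposure_s")))
  cat(sprintf("  value range [%d, %d], mean %.1f ADU\n",
              min(x), max(x), mean(x)))
  invisible(x)
}
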