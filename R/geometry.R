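#' Phosphor point-spread model
#'
#' Radial point-spread function of the phosphor (plus the slight additional
#' blur of the optical chain), modelled as a two-component mixture: a 2-D
#' Gaussian core and an isotropic exponential tail. Each emitted light photon
#' is displaced from its parent X-ray impact by one draw from this mixture.
#'
#' The full-system point spread (phosphor plus optical chain) is slightly
#' wider than the phosphor's own point spread, whose widths are bounded by
#' FWHM < 40 um and FW10%M < 100 um; the defaults (24% core of sigma
#' 15.5 um, 76% exponential tail of scale 30 um) place the sampled profile
#' just inside those bounds, at FWHM ~= 38 um and FW10%M ~= 95 um.
#' [psf_widths()] evaluates both widths numerically.
#'
#' @param core_frac fraction of light in the Gaussian core, in [0, 1].
#' @param core_sigma_um sigma of the Gaussian core, um.
#' @param tail_scale_um scale of the exponential tail (2-D intensity
#'   proportional to `exp(-r/scale)`), um.
#' @return an object of class `psf_model`.
#' @export
psf_model <- function(core_frac = 0.24, core_sigma_um = 15.5,
                      tail_scale_um = 30) {
  stopifnot(core_frac >= 0, core_frac <= 1,
            core_sigma_um > 0, tail_scale_um > 0)
  structure(list(core_frac = core_frac, core_sigma_um = core_sigma_um,
                 tail_scale_um = tail_scale_um),
            class = "psf_model")
}

#' Sample light-photon displacements from the point-spread model
#'
#' @param n number of displacements.
#' @param psf a [psf_model()].
#' @return an `n x 2` matrix of (dx, dy) displacements in um.
#' @export
psf_sample <- function(n, psf) {
  stopifnot(inherits(psf, "psf_model"))
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  core <- stats::runif(n) < psf$core_frac
  dx <- numeric(n); dy <- numeric(n)
  nc <- sum(core)
  if (nc > 0L) {
    dx[core] <- stats::rnorm(nc, 0, psf$core_sigma_um)
    dy[core] <- stats::rnorm(nc, 0, psf$core_sigma_um)
  }
  nt <- n - nc
  if (nt > 0L) {
    # 2-D density ~ exp(-r/s)  <=>  radius ~ Gamma(shape 2, scale s)
    r <- stats::rgamma(nt, shape = 2, scale = psf$tail_scale_um)
    th <- stats::runif(nt, 0, 2 * pi)
    dx[!core] <- r * cos(th)
    dy[!core] <- r * sin(th)
  }
  cbind(dx, dy)
}

#' Radial intensity profile of the point-spread model
#'
#' @param r radii in um (vectorized).
#' @param psf a [psf_model()].
#' @return intensity per unit area at radius `r` (integrates to 1 over the
#'   plane).
#' @export
psf_radial_intensity <- function(r, psf) {
  stopifnot(inherits(psf, "psf_model"))
  s <- psf$core_sigma_um; l <- psf$tail_scale_um
  psf$core_frac * exp(-r^2 / (2 * s^2)) / (2 * pi * s^2) +
    (1 - psf$core_frac) * exp(-r / l) / (2 * pi * l^2)
}

#' Full widths of the point-spread profile
#'
#' Numerically evaluates the full width at half maximum and at 10% maximum of
#' the radial intensity profile.
#'
#' @param psf a [psf_model()].
#' @return named vector `c(fwhm_um, fw10m_um)`.
#' @export
psf_widths <- function(psf) {
  peak <- psf_radial_intensity(0, psf)
  half_r <- function(frac) {
    stats::uniroot(function(r) psf_radial_intensity(r, psf) - frac * peak,
                   interval = c(1e-9, 50 * (psf$core_sigma_um +
                                              psf$tail_scale_um)))$root
  }
  c(fwhm_um = 2 * half_r(0.5), fw10m_um = 2 * half_r(0.1))
}

#' Fibre-optic taper model
#'
#' Geometry of the demagnifying taper: linear demagnification plus a radially
#' symmetric cubic distortion about the detector centre,
#' \deqn{r_{ccd} = (r_{face}/\mathrm{demag})\,(1 + k_2\,r_{face}^2),}
#' a pincushion for `k2 > 0`. Instead of `k2` directly, the distortion can be
#' specified as the maximal (corner) displacement in corrected pixels that the
#' cubic term produces when referred back to the detector face.
#'
#' Coordinates: face pixels are 73 um squares and CCD pixels 30 um squares,
#' both indexed 1-based with pixel `i` spanning `[(i-1)p, ip)` um and centred
#' at `(i - 0.5) p`; the mapping is radial about the centre of each grid.
#'
#' @param demag linear demagnification ratio (> 1).
#' @param max_edge_displacement_px maximal face-equivalent displacement of the
#'   cubic term, in corrected (face) pixels, evaluated at the face corner.
#'   Ignored when `k2` is given.
#' @param k2 cubic distortion coefficient, um^-2; overrides
#'   `max_edge_displacement_px` when non-`NULL`.
#' @param face_pixel_um,ccd_pixel_um pixel pitches, um.
#' @param n_face,n_ccd grid sizes in pixels.
#' @return an object of class `taper_model`. Monotonicity (bijectivity) of the
#'   radial mapping over the face is checked at construction.
#' @export
taper_model <- function(demag = 2.7, max_edge_displacement_px = 3, k2 = NULL,
                        face_pixel_um = 73, ccd_pixel_um = 30,
                        n_face = 1024L, n_ccd = 1024L) {
  stopifnot(demag > 1, face_pixel_um > 0, ccd_pixel_um > 0)
  r_corner <- sqrt(2) * n_face * face_pixel_um / 2
  if (is.null(k2))
    k2 <- max_edge_displacement_px * face_pixel_um / r_corner^3
  # bijectivity: d r_ccd / d r_face = (1 + 3 k2 r^2)/demag > 0 on [0, corner]
  rr <- seq(0, r_corner, length.out = 256L)
  if (any(1 + 3 * k2 * rr^2 <= 0))
    stop("distortion mapping is not monotone over the face; ",
         "choose a smaller |k2|", call. = FALSE)
  structure(list(demag = demag, k2 = k2,
                 face_pixel_um = face_pixel_um, ccd_pixel_um = ccd_pixel_um,
                 n_face = as.integer(n_face), n_ccd = as.integer(n_ccd),
                 face_center_um = n_face * face_pixel_um / 2,
                 ccd_center_um = n_ccd * ccd_pixel_um / 2),
            class = "taper_model")
}

#' Map detector-face positions to CCD positions
#'
#' @param xy `n x 2` matrix of face positions, um from the face corner.
#' @param taper a [taper_model()].
#' @return `n x 2` matrix of CCD positions, um from the CCD corner.
#' @export
face_to_ccd <- function(xy, taper) {
  stopifnot(inherits(taper, "taper_model"))
  dx <- xy[, 1L] - taper$face_center_um
  dy <- xy[, 2L] - taper$face_center_um
  f <- (1 + taper$k2 * (dx * dx + dy * dy)) / taper$demag
  cbind(taper$ccd_center_um + f * dx, taper$ccd_center_um + f * dy)
}

#' Map CCD positions back along the taper to the detector face
#'
#' Numerical inverse of [face_to_ccd()] (Newton iterations on the radial
#' cubic; converges to machine precision in a handful of steps for the mild
#' distortions used here).
#'
#' @param xy `n x 2` matrix of CCD positions, um from the CCD corner.
#' @param taper a [taper_model()].
#' @return `n x 2` matrix of face positions, um from the face corner.
#' @export
ccd_to_face <- function(xy, taper) {
  stopifnot(inherits(taper, "taper_model"))
  dx <- xy[, 1L] - taper$ccd_center_um
  dy <- xy[, 2L] - taper$ccd_center_um
  rc <- sqrt(dx * dx + dy * dy)
  rf <- rc * taper$demag  # initial guess: undistorted
  k2 <- taper$k2; demag <- taper$demag
  for (i in 1:12) {
    g <- rf * (1 + k2 * rf^2) / demag - rc
    gp <- (1 + 3 * k2 * rf^2) / demag
    step <- g / gp
    rf <- rf - step
    if (max(abs(step), 0) < 1e-10) break
  }
  scale <- ifelse(rc > 0, rf / rc, demag)
  cbind(taper$face_center_um + scale * dx, taper$face_center_um + scale * dy)
}

#' Detector configuration
#'
#' Complete description of the simulated detector: cascade stage parameters,
#' grid geometry, taper, point-spread model, CCD bias and dark-current rate,
#' and the pedestal re-added to corrected images for storage.
#'
#' @param params a [cascade_params()].
#' @param taper a [taper_model()].
#' @param psf a [psf_model()].
#' @param bias_adu constant ADC offset added to raw pixel values, ADU.
#' @param dark_e_per_px_s dark-current accumulation rate, electrons per pixel
#'   per second.
#' @param pedestal_adu pedestal offset re-added to corrected images, ADU.
#' @param energy_keV X-ray energy (monoenergetic, normal incidence).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(params = cascade_params(),
                            taper = taper_model(),
                            psf = psf_model(),
                            bias_adu = 500,
                            dark_e_per_px_s = 0.01,
                            pedestal_adu = 10,
                            energy_keV = 12) {
  stopifnot(inherits(params, "cascade_params"),
            inherits(taper, "taper_model"),
            inherits(psf, "psf_model"),
            bias_adu >= 0, dark_e_per_px_s >= 0)
  structure(list(params = params, taper = taper, psf = psf,
                 bias_adu = bias_adu, dark_e_per_px_s = dark_e_per_px_s,
                 pedestal_adu = pedestal_adu, energy_keV = energy_keV),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("p-t-CCD detector configuration\n")
  cat(sprintf("  face grid : %d x %d px of %g um\n",
              x$taper$n_face, x$taper$n_face, x$taper$face_pixel_um))
  cat(sprintf("  CCD grid  : %d x %d px of %g um, demag %g:1, k2 = %.3e um^-2\n",
              x$taper$n_ccd, x$taper$n_ccd, x$taper$ccd_pixel_um,
              x$taper$demag, x$taper$k2))
  cat(sprintf("  bias %g ADU, dark %g e-/px/s, pedestal %g ADU, %g keV\n",
              x$bias_adu, x$dark_e_per_px_s, x$pedestal_adu, x$energy_keV))
  print(x$params)
  invisible(x)
}

#' Write / read a detector configuration as a key-value file
#'
#' Plain `key = value` text serialization of every scalar in the
#' configuration; round-trips losslessly at full double precision.
#'
#' @param config a [detector_config()].
#' @param path file path.
#' @return `read_config` returns a [detector_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "detector_config"))
  kv <- c(
    q_abs = config$params$q_abs, gain_mean = config$params$gain_mean,
    gain_sd = config$params$gain_sd, transmission = config$params$transmission,
    e_yield = config$params$e_yield, g_adc = config$params$g_adc,
    read_noise_e = config$params$read_noise_e,
    digitization_var_adu2 = config$params$digitization_var_adu2,
    demag = config$taper$demag, k2 = config$taper$k2,
    face_pixel_um = config$taper$face_pixel_um,
    ccd_pixel_um = config$taper$ccd_pixel_um,
    n_face = config$taper$n_face, n_ccd = config$taper$n_ccd,
    psf_core_frac = config$psf$core_frac,
    psf_core_sigma_um = config$psf$core_sigma_um,
    psf_tail_scale_um = config$psf$tail_scale_um,
    bias_adu = config$bias_adu, dark_e_per_px_s = config$dark_e_per_px_s,
    pedestal_adu = config$pedestal_adu, energy_keV = config$energy_keV)
  writeLines(sprintf("%s = %.17g", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  kv <- stats::setNames(as.numeric(trimws(vapply(parts, `[`, "", 2L))),
                        trimws(vapply(parts, `[`, "", 1L)))
  detector_config(
    params = cascade_params(
      q_abs = kv[["q_abs"]], gain_mean = kv[["gain_mean"]],
      gain_sd = kv[["gain_sd"]], transmission = kv[["transmission"]],
      e_yield = kv[["e_yield"]], g_adc = kv[["g_adc"]],
      read_noise_e = kv[["read_noise_e"]],
      digitization_var_adu2 = kv[["digitization_var_adu2"]]),
    taper = taper_model(demag = kv[["demag"]], k2 = kv[["k2"]],
                        face_pixel_um = kv[["face_pixel_um"]],
                        ccd_pixel_um = kv[["ccd_pixel_um"]],
                        n_face = kv[["n_face"]], n_ccd = kv[["n_ccd"]]),
    psf = psf_model(core_frac = kv[["psf_core_frac"]],
                    core_sigma_um = kv[["psf_core_sigma_um"]],
                    tail_scale_um = kv[["psf_tail_scale_um"]]),
    bias_adu = kv[["bias_adu"]], dark_e_per_px_s = kv[["dark_e_per_px_s"]],
    pedestal_adu = kv[["pedestal_adu"]], energy_keV = kv[["energy_keV"]])
}
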