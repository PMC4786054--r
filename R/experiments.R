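#' Specification of a replicate spot-image ensemble
#'
#' Describes the study conditions for an ensemble of simulated spot images: a
#' two-dimensional Gaussian spot with Poisson-distributed total photon count
#' on a uniform Poisson flood background, recorded in one of two detector
#' zones, and integrated with a MOSFLM-style measurement box. Zone A centres
#' the box at face pixel (306, 306); zone B shifts the spot (and box) by six
#' face pixels in X and Y to (300, 300), sampling a different registration of
#' the raw and corrected pixel grids.
#'
#' Box parameters are quoted in face-grid (corrected-image, 73 um) pixels;
#' when integrating raw images they are converted to the raw pixel pitch
#' with [convert_box_params()] so the box subtends the same physical region.
#'
#' @param n_replicates number of replicate images.
#' @param spot_mean mean total X-ray count of the spot.
#' @param spot_sigma_um Gaussian spread of the spot at the face, um. The
#'   default keeps >99.9% of the spot light inside the peak region of both
#'   the corrected and the raw measurement boxes.
#' @param bg_per_pixel mean background X-rays per 73 um face pixel.
#' @param zone `"A"` or `"B"`, or a length-2 integer face-pixel centre.
#' @param box named list of face-unit box parameters
#'   (`nx`, `ny`, `nrx`, `nry`, `nc`).
#' @param exposure_s exposure length per image, seconds.
#' @param window_margin_px extra face pixels simulated around the box so
#'   that point-spread leakage across the region edge is modelled.
#' @param seed integer seed for the ensemble run.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_replicates = 1000L,
                          spot_mean = 1e4,
                          spot_sigma_um = 80,
                          bg_per_pixel = 20,
                          zone = "A",
                          box = list(nx = 23L, ny = 23L, nrx = 5L,
                                     nry = 4L, nc = 11L),
                          exposure_s = 1,
                          window_margin_px = 4L,
                          seed = 1L) {
  center <- if (is.character(zone)) {
    switch(match.arg(zone, c("A", "B")),
           A = c(306L, 306L), B = c(300L, 300L))
  } else as.integer(zone)
  structure(list(n_replicates = as.integer(n_replicates),
                 spot_mean = spot_mean, spot_sigma_um = spot_sigma_um,
                 bg_per_pixel = bg_per_pixel, zone = zone,
                 center_face_px = center, box = box,
                 exposure_s = exposure_s,
                 window_margin_px = as.integer(window_margin_px),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# precompute every geometric and calibration object an ensemble run needs
ensemble_geometry <- function(spec, config, pipeline,
                              n_dark_images = 200L, n_flood_images = 100L,
                              flood_mean = 100) {
  tp <- config$taper
  p_face <- tp$face_pixel_um
  center_um <- (spec$center_face_px - 0.5) * p_face
  m <- spec$window_margin_px

  geom <- list(config = config, spec = spec, pipeline = pipeline,
               center_um = center_um, budget = noise_budget(config$params))

  if (pipeline == "corrected") {
    hx <- (spec$box$nx - 1) / 2; hy <- (spec$box$ny - 1) / 2
    # corrected-grid window around the box
    cwin <- list(x = c(spec$center_face_px[1L] - hx - m,
                       spec$center_face_px[1L] + hx + m),
                 y = c(spec$center_face_px[2L] - hy - m,
                       spec$center_face_px[2L] + hy + m))
    # raw pixels needed: those whose quads can touch the corrected window
    corners_um <- as.matrix(expand.grid(
      x = (c(cwin$x[1L] - 1, cwin$x[2L])) * p_face,
      y = (c(cwin$y[1L] - 1, cwin$y[2L])) * p_face))
    ccd <- face_to_ccd(corners_um, tp)
    rwin <- list(
      x = c(floor(min(ccd[, 1L]) / tp$ccd_pixel_um) - 1L,
            ceiling(max(ccd[, 1L]) / tp$ccd_pixel_um) + 2L),
      y = c(floor(min(ccd[, 2L]) / tp$ccd_pixel_um) - 1L,
            ceiling(max(ccd[, 2L]) / tp$ccd_pixel_um) + 2L))
    geom$cwin <- cwin
    geom$box <- measurement_box(spec$center_face_px, spec$box$nx,
                                spec$box$ny, spec$box$nrx, spec$box$nry,
                                spec$box$nc)
    geom$pedestal <- config$pedestal_adu
  } else {
    pitch_at_face <- tp$demag * tp$ccd_pixel_um
    bp <- convert_box_params(spec$box$nx, spec$box$ny, spec$box$nrx,
                             spec$box$nry, spec$box$nc,
                             scale = p_face / pitch_at_face)
    ccd_c <- face_to_ccd(matrix(center_um, 1L), tp)
    raw_center <- as.integer(floor(ccd_c / tp$ccd_pixel_um) + 1L)
    geom$box <- measurement_box(raw_center, bp$nx, bp$ny, bp$nrx, bp$nry,
                                bp$nc)
    geom$pedestal <- config$bias_adu
    geom$n_raw_peak <- geom$box$M
    geom$n_raw_bg <- geom$box$N
    rwin <- list(x = raw_center[1L] + c(-1L, 1L) * ((bp$nx - 1L) %/% 2L + m),
                 y = raw_center[2L] + c(-1L, 1L) * ((bp$ny - 1L) %/% 2L + m))
  }
  rwin <- lapply(rwin, as.integer)
  geom$rwin <- rwin
  pw <- face_photon_window(config, rwin)
  geom$pwin <- pw$pwin
  geom$flood_x0 <- pw$x0
  geom$flood_y0 <- pw$y0

  geom$dark <- build_dark(config, spec$exposure_s, n_dark_images,
                          window = rwin)
  if (pipeline == "corrected") {
    geom$map <- build_distortion_map(tp, rwin)
    geom$S <- redistribution_matrix(geom$map, geom$cwin)
    floods <- replicate(n_flood_images,
                        engine_image(geom, spot_mean = 0,
                                     bg_mean = flood_mean, kind = "flood"),
                        simplify = FALSE)
    geom$flat <- build_flat_field(floods, geom$dark, geom$map)
    # exact effective raw-pixel counts behind the peak and background
    npx <- geom$cwin$x[2L] - geom$cwin$x[1L] + 1L
    local_idx <- function(mask) {
      ii <- spec$center_face_px[1L] + geom$box$dx[mask] - geom$cwin$x[1L] + 1L
      jj <- spec$center_face_px[2L] + geom$box$dy[mask] - geom$cwin$y[1L] + 1L
      ii + npx * (jj - 1L)
    }
    geom$n_raw_peak <- effective_raw_pixels(geom$S,
                                            local_idx(geom$box$peak))[["effective"]]
    geom$n_raw_bg <- effective_raw_pixels(geom$S,
                                          local_idx(geom$box$background))[["effective"]]
  }
  geom
}

# photon-generation window for a raw-pixel window: the face pixels whose
# light can reach it, i.e. the back-projected extent plus a point-spread
# margin; also returns the face-um base coordinate of every window pixel
face_photon_window <- function(config, rwin) {
  tp <- config$taper
  p_face <- tp$face_pixel_um
  fext <- ccd_to_face(as.matrix(expand.grid(
    x = (rwin$x - c(1L, 0L)) * tp$ccd_pixel_um,
    y = (rwin$y - c(1L, 0L)) * tp$ccd_pixel_um)), tp)
  psf_margin <- 4 * (config$psf$core_sigma_um + config$psf$tail_scale_um)
  pwin <- list(
    x = as.integer(c(floor((min(fext[, 1L]) - psf_margin) / p_face) + 1L,
                     ceiling((max(fext[, 1L]) + psf_margin) / p_face))),
    y = as.integer(c(floor((min(fext[, 2L]) - psf_margin) / p_face) + 1L,
                     ceiling((max(fext[, 2L]) + psf_margin) / p_face))))
  fx <- (pwin$x[1L]:pwin$x[2L] - 1) * p_face
  fy <- (pwin$y[1L]:pwin$y[2L] - 1) * p_face
  list(pwin = pwin, x0 = rep(fx, times = length(fy)),
       y0 = rep(fy, each = length(fx)))
}

# fast flood exposure of a raw-pixel window through the fused engine path
simulate_flood_image <- function(config, rwin, mean_per_pixel,
                                 exposure_s = 1, kind = "flood") {
  pw <- face_photon_window(config, rwin)
  geom <- list(config = config,
               spec = list(exposure_s = exposure_s, spot_mean = 0,
                           spot_sigma_um = 1),
               center_um = c(0, 0), rwin = rwin,
               flood_x0 = pw$x0, flood_y0 = pw$y0)
  engine_image(geom, spot_mean = 0, bg_mean = mean_per_pixel, kind = kind)
}

# Fused phosphor + taper + CCD path for one replicate. Two exact
# distributional identities keep this fast without changing the model:
# (i) Poisson thinning — the absorbed X-rays of a Poisson flux are again
# Poisson with mean q_abs * flux, so absorbed photons are generated
# directly; (ii) binomial thinning — each emitted light photon survives the
# optics independently, so point-spread displacements are only drawn for
# survivors. The staged functions (phosphor_stage etc.) realise the same
# chain event by event.
engine_image <- function(geom, spot_mean = geom$spec$spot_mean,
                         bg_mean = geom$spec$bg_per_pixel, kind = "raw") {
  cfg <- geom$config
  pars <- cfg$params
  tp <- cfg$taper
  p_face <- tp$face_pixel_um
  # absorbed X-ray positions
  n_s <- if (spot_mean > 0)
    stats::rpois(1L, spot_mean * pars$q_abs) else 0L
  if (n_s > 0L) {
    sx <- stats::rnorm(n_s, geom$center_um[1L], geom$spec$spot_sigma_um)
    sy <- stats::rnorm(n_s, geom$center_um[2L], geom$spec$spot_sigma_um)
  } else sx <- sy <- numeric(0)
  if (bg_mean > 0) {
    cnt <- stats::rpois(length(geom$flood_x0), bg_mean * pars$q_abs)
    nb <- sum(cnt)
    bx <- rep.int(geom$flood_x0, cnt) + p_face * stats::runif(nb)
    by <- rep.int(geom$flood_y0, cnt) + p_face * stats::runif(nb)
  } else bx <- by <- numeric(0)
  x <- c(sx, bx); y <- c(sy, by)
  n_abs <- length(x)
  counts <- if (n_abs > 0L) {
    # scintillation gain and survival of each light photon through the optics
    k <- if (pars$gain_sd > 0) {
      shape <- (pars$gain_mean / pars$gain_sd)^2
      round(stats::rgamma(n_abs, shape = shape,
                          scale = pars$gain_mean / shape))
    } else rep.int(round(pars$gain_mean), n_abs)
    s <- stats::rbinom(n_abs, k, pars$transmission)
    parent <- rep.int(seq_len(n_abs), s)
    nl <- length(parent)
    # point spread: Gaussian core with exponential-tail overwrite
    psf <- cfg$psf
    dx <- stats::rnorm(nl, 0, psf$core_sigma_um)
    dy <- stats::rnorm(nl, 0, psf$core_sigma_um)
    tail_i <- which(stats::runif(nl) >= psf$core_frac)
    if (length(tail_i)) {
      r <- stats::rgamma(length(tail_i), shape = 2,
                         scale = psf$tail_scale_um)
      th <- stats::runif(length(tail_i), 0, 2 * pi)
      dx[tail_i] <- r * cos(th)
      dy[tail_i] <- r * sin(th)
    }
    lx <- x[parent] + dx - tp$face_center_um
    ly <- y[parent] + dy - tp$face_center_um
    # taper mapping, face -> CCD
    f <- (1 + tp$k2 * (lx * lx + ly * ly)) / tp$demag
    nx <- geom$rwin$x[2L] - geom$rwin$x[1L] + 1L
    ny <- geom$rwin$y[2L] - geom$rwin$y[1L] + 1L
    ix <- floor((tp$ccd_center_um + f * lx) / tp$ccd_pixel_um) -
      geom$rwin$x[1L] + 2
    iy <- floor((tp$ccd_center_um + f * ly) / tp$ccd_pixel_um) -
      geom$rwin$y[1L] + 2
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    tabulate(ix[ok] + nx * (iy[ok] - 1), nbins = nx * ny)
  } else {
    numeric((geom$rwin$x[2L] - geom$rwin$x[1L] + 1L) *
              (geom$rwin$y[2L] - geom$rwin$y[1L] + 1L))
  }
  ccd_readout(counts, geom$rwin, geom$spec$exposure_s, cfg, kind)
}

# one replicate image in the requested pipeline
replicate_image <- function(geom) {
  raw <- engine_image(geom)
  if (geom$pipeline == "corrected")
    correct_image(raw, geom$dark, geom$flat, map = geom$map, S = geom$S,
                  pedestal_adu = geom$config$pedestal_adu)
  else raw
}

#' Run a replicate spot-image ensemble
#'
#' Generates `spec$n_replicates` replicate spot images (plus a separate set
#' used only to build the reference profile), integrates every replicate by
#' summation and by diagonal-weight profile fitting, and evaluates the
#' independent-Poisson and cascade-model variance estimators for each.
#'
#' For the corrected pipeline a dark, an area-scaled flat field and the
#' distortion-correction operator are built once from their own simulated
#' calibration exposures, and every replicate passes through the full
#' correction chain; raw-pixel counts behind the peak and background regions
#' are computed exactly from the distortion map.
#'
#' @param spec an [ensemble_spec()].
#' @param config a [detector_config()].
#' @param pipeline `"raw"` or `"corrected"`.
#' @param methods integration methods to run (`"summation"`,
#'   `"profile"`).
#' @param n_profile_images replicates used to build the reference profile
#'   (not part of the ensemble statistics).
#' @param keep_rasters keep each replicate's measurement-box raster (needed
#'   for [empirical_pixel_covariance()] and GLS refits).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return an object of class `spot_ensemble` with the per-replicate results
#'   data frame, the geometry, reference profile, and (optionally) the box
#'   rasters. Summarize with [summary.spot_ensemble()].
#' @export
run_spot_ensemble <- function(spec, config = detector_config(),
                              pipeline = c("raw", "corrected"),
                              methods = c("summation", "profile"),
                              n_profile_images = 20L,
                              keep_rasters = FALSE,
                              seed = spec$seed) {
  pipeline <- match.arg(pipeline)
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  geom <- ensemble_geometry(spec, config, pipeline)
  box <- geom$box
  ped <- geom$pedestal

  do_profile <- "profile" %in% methods
  fitter <- NULL; profile <- NULL
  if (do_profile) {
    prof_imgs <- replicate(n_profile_images, replicate_image(geom),
                           simplify = FALSE)
    profile <- build_reference_profile(prof_imgs, box, ped)
    bg_level <- mean(vapply(prof_imgs, function(im)
      fit_background_plane(im, box, ped)$c, 0))
    fitter <- profile_fitter(box, profile, "diagonal",
                             bg_level = max(bg_level, 1))
  }

  n <- spec$n_replicates
  i_s <- numeric(n); v_pois <- numeric(n); v_casc <- numeric(n)
  i_p <- rep(NA_real_, n); v_prof <- rep(NA_real_, n)
  rasters <- if (keep_rasters) matrix(0, n, box$nx * box$ny) else NULL
  for (r in seq_len(n)) {
    img <- replicate_image(geom)
    res <- summation_integrate(img, box, pedestal = ped)
    i_s[r] <- res$intensity
    v_pois[r] <- variance_poisson_mosflm(res, geom$budget$gain_absorbed)
    v_casc[r] <- variance_cascade(res, geom$budget, geom$n_raw_peak,
                                  geom$n_raw_bg)
    if (do_profile || keep_rasters) {
      rho <- box_values(img, box, ped)
      if (keep_rasters) rasters[r, ] <- as.numeric(rho)
      if (do_profile) {
        pf <- fitter(rho)
        i_p[r] <- pf$intensity
        v_prof[r] <- pf$variance
      }
    }
  }
  structure(list(results = data.frame(i_s = i_s, var_poisson = v_pois,
                                      var_cascade = v_casc, i_p = i_p,
                                      var_profile_diag = v_prof),
                 spec = spec, pipeline = pipeline, box = box,
                 pedestal = ped, profile = profile, rasters = rasters,
                 geometry = geom, seed = seed),
            class = "spot_ensemble")
}

#' Summarize a spot ensemble
#'
#' Ensemble statistics in the layout of the replicate-spot study: mean and
#' observed variance of the summation intensities, the ensemble means of the
#' two summation variance estimators, and (when profile fitting was run) the
#' same for profile-fitted intensities together with the ratio of observed
#' variance to mean estimated variance. Standard errors of each statistic
#' accompany the values.
#'
#' @param object a [run_spot_ensemble()] result.
#' @param ... unused.
#' @return a list of class `spot_ensemble_summary` with components
#'   `summation`, `profile` (each value/SE pairs) and `n`.
#' @export
summary.spot_ensemble <- function(object, ...) {
  x <- object$results
  n <- nrow(x)
  se_mean <- function(v) stats::sd(v) / sqrt(n)
  se_var <- function(v) stats::var(v) * sqrt(2 / (n - 1))
  s <- list(
    mean_i_s = c(value = mean(x$i_s), se = se_mean(x$i_s)),
    var_i_s = c(value = stats::var(x$i_s), se = se_var(x$i_s)),
    mean_var_poisson = c(value = mean(x$var_poisson),
                         se = se_mean(x$var_poisson)),
    mean_var_cascade = c(value = mean(x$var_cascade),
                         se = se_mean(x$var_cascade)))
  pr <- NULL
  if (!all(is.na(x$i_p))) {
    ratio <- stats::var(x$i_p) / mean(x$var_profile_diag)
    pr <- list(
      mean_i_p = c(value = mean(x$i_p), se = se_mean(x$i_p)),
      var_i_p = c(value = stats::var(x$i_p), se = se_var(x$i_p)),
      mean_var_diag = c(value = mean(x$var_profile_diag),
                        se = se_mean(x$var_profile_diag)),
      ratio_obs_est = c(value = ratio, se = ratio * sqrt(2 / (n - 1))))
  }
  structure(list(summation = s, profile = pr, n = n,
                 pipeline = object$pipeline, zone = object$spec$zone),
            class = "spot_ensemble_summary")
}

#' @export
print.spot_ensemble_summary <- function(x, ...) {
  cat(sprintf("spot ensemble (%s pipeline, zone %s, n = %d)\n",
              x$pipeline, paste(x$zone, collapse = ","), x$n))
  fmt <- function(nm, v) cat(sprintf("  %-22s %12.1f (%.1f)\n", nm,
                                     v[["value"]], v[["se"]]))
  fmt("mean(I_S) [ADU]", x$summation$mean_i_s)
  fmt("var(I_S) [ADU^2]", x$summation$var_i_s)
  fmt("mean Poisson est.", x$summation$mean_var_poisson)
  fmt("mean cascade est.", x$summation$mean_var_cascade)
  if (!is.null(x$profile)) {
    fmt("mean(I_P) [ADU]", x$profile$mean_i_p)
    fmt("var(I_P) [ADU^2]", x$profile$var_i_p)
    fmt("mean diag. prof. est.", x$profile$mean_var_diag)
    cat(sprintf("  %-22s %12.2f (%.2f)\n", "var/mean-est ratio",
                x$profile$ratio_obs_est[["value"]],
                x$profile$ratio_obs_est[["se"]]))
  }
  invisible(x)
}

#' @export
print.spot_ensemble <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Detector gain from simultaneous scintillation counting
#'
#' Estimates the incident-photon gain G' as the slope of a
#' through-the-origin linear fit of integrated spot intensity against
#' scintillation-counter photon counts, rescaled by the relative-intensity
#' factor between the monitored and the imaged spot. The reported standard
#' error combines the slope fit with the uncertainty of the relative factor.
#'
#' @param intensity_sums integrated intensities of the imaged spot, ADU.
#' @param photon_counts background-subtracted scintillation counts of the
#'   monitored spot.
#' @param relative_factor intensity of the imaged spot relative to the
#'   monitored spot (imaged / monitored).
#' @param relative_factor_se standard error of `relative_factor`.
#' @return named vector `c(gain, se)`: G' in ADU per incident photon.
#' @export
gain_from_counting <- function(intensity_sums, photon_counts,
                               relative_factor = 1,
                               relative_factor_se = 0) {
  if (length(intensity_sums) != length(photon_counts))
    stop("series lengths differ", call. = FALSE)
  if (length(intensity_sums) < 3L)
    stop("need at least 3 exposures", call. = FALSE)
  # intensity of the *monitored* spot inferred from the imaged one
  y <- intensity_sums / relative_factor
  x <- photon_counts
  slope <- sum(x * y) / sum(x * x)
  r <- y - slope * x
  se_slope <- sqrt(sum(r^2) / (length(x) - 1L) / sum(x * x))
  se <- abs(slope) * sqrt((se_slope / slope)^2 +
                            (relative_factor_se / relative_factor)^2)
  c(gain = slope, se = se)
}

#' Total pixel noise of a measurement box from dark images
#'
#' Sample variance of the measurement-box sum over a series of corrected (or
#' raw, bias is irrelevant to a variance) images recorded with no beam: the
#' total read-out plus digitization noise `N psi` for that box.
#'
#' @param images list of `ptccd_image`s with no X-ray signal.
#' @param box a [measurement_box()] (the whole box, peak and background,
#'   is summed).
#' @return variance of the box sum, ADU^2.
#' @export
pixel_noise_from_darks <- function(images, box) {
  stopifnot(length(images) >= 2L)
  sums <- vapply(images, function(im) sum(box_values(im, box, 0)), 0)
  stats::var(sums)
}

#' Response series of repeated exposures with a beam monitor
#'
#' @param intensity integrated intensities per exposure, ADU.
#' @param monitor background-subtracted beam-monitor readings (arbitrary
#'   units, proportional to dose).
#' @param section integer/factor id of the contiguous well-behaved segment
#'   each exposure belongs to (segments demarcated by abrupt beam changes).
#' @return an object of class `response_series`.
#' @export
response_series <- function(intensity, monitor,
                            section = rep(1L, length(intensity))) {
  stopifnot(length(intensity) == length(monitor),
            length(section) == length(intensity))
  structure(data.frame(intensity = intensity, monitor = monitor,
                       section = as.integer(factor(section))),
            class = c("response_series", "data.frame"))
}

#' Trend removal and residual variance of a response series
#'
#' Within each section, the intensity trend is modelled as a linear scaling
#' of the monitor readings (fit through the origin: dose-proportional
#' response); the response variance is the pooled variance of the residuals
#' about the per-section trends (unweighted pooling across sections). The
#' signal level is the mean of the fitted trend. A diagnostic flag reports
#' whether the trend varies little enough (SD below `trend_cv_warn` of its
#' mean) for the stationary-variance approximation to hold.
#'
#' @param series a [response_series()].
#' @param trend_cv_warn warn when the trend's coefficient of variation
#'   exceeds this value.
#' @return list with `signal_mean` (ADU), `residual_variance` (ADU^2),
#'   `trend_cv`, and the per-section scale factors.
#' @export
trend_residual_variance <- function(series, trend_cv_warn = 0.05) {
  stopifnot(inherits(series, "response_series"))
  secs <- split(seq_len(nrow(series)), series$section)
  if (any(vapply(secs, length, 0L) < 3L))
    stop("every section needs at least 3 exposures", call. = FALSE)
  fitted <- numeric(nrow(series)); scales <- numeric(length(secs))
  for (k in seq_along(secs)) {
    i <- secs[[k]]
    scales[k] <- sum(series$monitor[i] * series$intensity[i]) /
      sum(series$monitor[i]^2)
    fitted[i] <- scales[k] * series$monitor[i]
  }
  resid <- series$intensity - fitted
  df <- nrow(series) - length(secs)
  rv <- sum(resid^2) / df
  cv <- stats::sd(fitted) / mean(fitted)
  if (cv > trend_cv_warn)
    warning(sprintf(paste0("trend SD is %.1f%% of its mean; the ",
                           "stationary-variance approximation may be poor"),
                    100 * cv))
  list(signal_mean = mean(fitted), residual_variance = rv, trend_cv = cv,
       section_scales = scales)
}

#' Synthetic response-series fixture
#'
#' Generates the tabular data the real-detector workflow consumes: a beam
#' monitor with slow drift and abrupt section breaks (top-up style), and
#' integrated intensities scattered about the monitor-proportional trend
#' with the cascade + pixel noise variance `gamma * G * s + N psi`.
#'
#' @param gamma cascade factor of the emulated detector.
#' @param gain_absorbed absorbed-photon gain G, ADU/photon.
#' @param n_psi total pixel noise of the measurement box, ADU^2.
#' @param signal_mean mean integrated intensity, ADU.
#' @param n_exposures number of exposures.
#' @param n_sections number of trend sections.
#' @param drift fractional peak-to-peak slow drift of the beam within a
#'   section.
#' @param seed integer seed.
#' @return a [response_series()] with attribute `truth` (the generating
#'   parameters).
#' @export
make_response_fixture <- function(gamma = 1.41, gain_absorbed = 1.44,
                                  n_psi = 5454, signal_mean = 11926,
                                  n_exposures = 400L, n_sections = 4L,
                                  drift = 0.03, seed = 1L) {
  stopifnot(gamma >= 0, gain_absorbed > 0, n_psi >= 0, signal_mean > 0)
  set.seed(seed)
  n <- as.integer(n_exposures)
  section <- rep(seq_len(n_sections), length.out = n, each = ceiling(n / n_sections))[seq_len(n)]
  t_in_sec <- stats::ave(rep(1, n), section, FUN = cumsum)
  len_sec <- stats::ave(rep(1, n), section, FUN = sum)
  # top-up style: beam decays within each section, refilled at each break
  monitor <- (1 + drift * (0.5 - t_in_sec / len_sec)) *
    (1 + 0.01 * (section %% 2))
  trend <- signal_mean * monitor / mean(monitor)
  noise_sd <- sqrt(gamma * gain_absorbed * trend + n_psi)
  intensity <- trend + stats::rnorm(n, 0, noise_sd)
  out <- response_series(intensity, monitor, section)
  attr(out, "truth") <- c(gamma = gamma, gain_absorbed = gain_absorbed,
                          n_psi = n_psi, signal_mean = signal_mean)
  out
}
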