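test_that("spot and flood photon generators match their stated laws", {
  set.seed(11)
  # Poisson total count: mean over 1000 draws within 3 SE of 1e4
  counts <- replicate(1000, stats::rpois(1L, 1e4))
  ph <- generate_spot_photons(c(1000, 2000), 50, 1e4)
  counts[1] <- nrow(ph)
  expect_within_se(mean(counts), 1e4, sqrt(1e4 / 1000))
  # positional covariance is isotropic sigma^2 I
  big <- generate_spot_photons(c(1000, 2000), 50, 1e5)
  n <- nrow(big)
  expect_within_se(var(big$x_um), 2500, 2500 * sqrt(2 / n))
  expect_within_se(var(big$y_um), 2500, 2500 * sqrt(2 / n))
  expect_lt(abs(cor(big$x_um, big$y_um)), 3 / sqrt(n))
  # degenerate inputs
  expect_identical(nrow(generate_spot_photons(c(0, 0), 10, 0)), 0L)
  expect_identical(nrow(generate_flood_photons(0, list(x = c(1, 10),
                                                       y = c(1, 10)))), 0L)
})

test_that("flood pixel counts are Poisson at the requested mean", {
  set.seed(12)
  region <- list(x = c(1L, 100L), y = c(1L, 100L))
  ph <- generate_flood_photons(20, region, face_pixel_um = 73)
  ix <- floor(ph$x_um / 73); iy <- floor(ph$y_um / 73)
  counts <- tabulate(ix + 100 * iy + 1, nbins = 1e4)
  # chi-square against Poisson(20), pooling tails to keep expected counts up
  breaks <- c(-Inf, 8:32, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-Inf, 8:32, Inf), 20))
  test <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(test$p.value, 0.01)
  # positions are uniform within pixels
  frac <- ph$x_um / 73 - ix
  expect_within_se(mean(frac), 0.5, sd(frac) / sqrt(nrow(ph)))
})

test_that("phosphor stage reproduces absorption and scintillation moments", {
  set.seed(13)
  # absorbed fraction over 1e6 X-rays (unit gain keeps the light table small)
  p1 <- cascade_params(gain_mean = 1, gain_sd = 0)
  ph <- photon_table(runif(1e6, 0, 1000), runif(1e6, 0, 1000))
  st <- phosphor_stage(ph, p1, psf_model())
  expect_within_se(st$n_absorbed / 1e6, 0.85, sqrt(0.85 * 0.15 / 1e6))
  # scintillation spectrum moments at the reference gain
  ph2 <- photon_table(runif(2e4, 0, 1000), runif(2e4, 0, 1000))
  st2 <- phosphor_stage(ph2, cascade_params(q_abs = 1), psf_model())
  k <- st2$photons_per_event
  expect_within_se(mean(k), 281.5, 163.3 / sqrt(length(k)))
  # SD of a gamma-law draw: allow for sampling error of the SD itself
  expect_within_se(sd(k), 163.3, 163.3 * sqrt(1 / length(k)) * 1.5, k = 4)
  # deterministic limit: every X-ray emits exactly the mean
  st3 <- phosphor_stage(photon_table(1:10 * 10, 1:10 * 10),
                        cascade_params(q_abs = 1, gain_mean = 50,
                                       gain_sd = 0),
                        psf_model(core_frac = 1, core_sigma_um = 1e-6))
  expect_true(all(st3$photons_per_event == 50))
  expect_identical(nrow(st3$xy), 500L)
})

test_that("taper stage thins light binomially and drops off-CCD photons", {
  set.seed(14)
  light <- list(xy = cbind(runif(2e5, 30000, 45000),
                           runif(2e5, 30000, 45000)))
  out <- taper_stage(light, taper_model(), transmission = 0.01715)
  frac <- nrow(out$xy) / 2e5
  expect_within_se(frac, 0.01715, sqrt(0.01715 * 0.983 / 2e5))
  # photons beyond the CCD edge are dropped and counted
  edge <- list(xy = cbind(rep(-1e5, 100), rep(-1e5, 100)))
  out2 <- taper_stage(edge, taper_model(), transmission = 1)
  expect_identical(out2$n_dropped, 100L)
  expect_identical(nrow(out2$xy), 0L)
})

test_that("CCD read-out: bias, read noise, gain and 16-bit clipping", {
  cfg <- detector_config()
  none <- list(xy = matrix(numeric(0), 0, 2))
  img <- ccd_expose(none, 1, cfg, window = list(x = c(1, 50), y = c(1, 40)),
                    seed = 15)
  v <- as.numeric(unclass(img))
  # mean ~ bias, variance ~ psi (read noise + quantization)
  expect_within_se(mean(v), 500, sd(v) / sqrt(length(v)))
  expect_within_se(var(v), ref_budget()$psi,
                   var(v) * sqrt(2 / length(v)) + 0.01)
  # noiseless gain: 1000 electrons -> 700 ADU
  quiet <- detector_config(params = cascade_params(read_noise_e = 0),
                           dark_e_per_px_s = 0)
  one <- list(xy = matrix(rep(c(15.5, 15.5), each = 1000), ncol = 2))
  img2 <- ccd_expose(one, 1, quiet, window = list(x = c(1, 3), y = c(1, 3)))
  expect_identical(unclass(img2)[1, 1], 700L)
  # saturating input clips at the 16-bit maximum
  lots <- list(xy = matrix(rep(c(15.5, 15.5), each = 400000), ncol = 2))
  img3 <- ccd_expose(lots, 1, quiet, window = list(x = c(1, 3), y = c(1, 3)))
  expect_identical(unclass(img3)[1, 1], 65535L)
})

test_that("simulate_image is deterministic given the seed", {
  cfg <- detector_config()
  ph <- generate_spot_photons(c(22301.5, 22301.5), 80, 500, seed = 31)
  w <- list(x = c(315, 340), y = c(315, 340))
  a <- simulate_image(ph, cfg, window = w, seed = 77)
  b <- simulate_image(ph, cfg, window = w, seed = 77)
  expect_identical(unclass(a), unclass(b))
  c2 <- simulate_image(ph, cfg, window = w, seed = 78)
  expect_false(identical(unclass(a), unclass(c2)))
})

test_that("expected bias-corrected total equals incident flux times G'", {
  cfg <- detector_config()
  b <- ref_budget()
  w <- list(x = c(318, 335), y = c(318, 335))
  set.seed(16)
  n_rep <- 200
  totals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ph <- generate_spot_photons(c(22301.5, 22301.5), 60, 500)
    img <- simulate_image(ph, cfg, window = w)
    totals[i] <- sum(unclass(img)) - 500 * length(img)
  }
  expect_within_se(mean(totals), 500 * b$gain_incident,
                   sd(totals) / sqrt(n_rep))
})

test_that("point spread reallocates signal without changing totals", {
  # sharp vs default PSF: the region-sum mean is unchanged when the region
  # holds the whole spot
  w <- list(x = c(318, 335), y = c(318, 335))
  mean_total <- function(cfg, seed) {
    set.seed(seed)
    mean(replicate(150, {
      ph <- generate_spot_photons(c(22301.5, 22301.5), 60, 500)
      img <- simulate_image(ph, cfg, window = w)
      sum(unclass(img)) - 500 * length(img)
    }))
  }
  sharp <- detector_config(psf = psf_model(core_frac = 1,
                                           core_sigma_um = 1e-3))
  broad <- detector_config()
  m1 <- mean_total(sharp, 17)
  m2 <- mean_total(broad, 18)
  se <- sqrt(2) * 60 / sqrt(150)  # ~combined SE of the two means
  expect_lt(abs(m1 - m2), 3 * se)
})

test_that("region-sum variance follows the cascade model (Monte Carlo)", {
  # flood-only sub-region: var(sum) = gamma G mean + N psi, and inverting
  # for gamma recovers the configured cascade factor
  cfg <- detector_config()
  b <- ref_budget()
  spec <- ensemble_spec(n_replicates = 1, spot_mean = 0, bg_per_pixel = 30,
                        box = list(nx = 9, ny = 9, nrx = 1, nry = 1,
                                   nc = 99),
                        seed = 19)
  set.seed(19)
  geom <- ptccd:::ensemble_geometry(spec, cfg, "raw")
  n_rep <- 900
  rx <- 4:12; ry <- 4:12  # interior raw pixels of the window
  sums <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    img <- ptccd:::engine_image(geom)
    sums[i] <- sum(unclass(img)[rx, ry]) - 500 * length(rx) * length(ry)
  }
  npx <- length(rx) * length(ry)
  pred <- signal_variance_adu2(mean(sums), npx, b)
  se <- var(sums) * sqrt(2 / (n_rep - 1))
  expect_within_se(var(sums), pred, se)
  gam <- estimate_gamma(var(sums), mean(sums), npx * b$psi, b$gain_absorbed)
  expect_within_se(gam, b$gamma, b$gamma * sqrt(2 / (n_rep - 1)) * 1.1)
})
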