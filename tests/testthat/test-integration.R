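test_that("measurement-box masks follow the rim and corner-cut rules", {
  # minimal box: single peak pixel, 8 background
  b3 <- measurement_box(c(5, 5), 3, 3, 1, 1)
  expect_identical(c(b3$M, b3$N), c(1L, 8L))
  expect_true(b3$peak[2, 2])
  # the reference box geometry: counts fixed by the mask rules
  b <- measurement_box(c(306, 306), 23, 23, 5, 4, 11)
  expect_identical(c(b$M, b$N), c(183L, 346L))
  expect_identical(b$M + b$N, 23L * 23L)
  # mm symmetry: masks invariant under x -> -x and y -> -y
  expect_identical(b$peak, b$peak[b$nx:1, ])
  expect_identical(b$peak, b$peak[, b$ny:1])
  # corner-cut pixels are background, strictly beyond nc
  expect_true(all((abs(b$dx) + abs(b$dy) > 11)[b$peak] == FALSE))
  expect_error(measurement_box(c(1, 1), 4, 5), "odd")
  expect_error(measurement_box(c(1, 1), 5, 5, 3, 3), "no peak")
})

test_that("face-unit box parameters convert to the raw pixel pitch", {
  expect_identical(convert_box_params(23, 23, 5, 4, 11, 1),
                   list(nx = 23L, ny = 23L, nrx = 5L, nry = 4L, nc = 11L))
  # raw pixels subtend demag * 30 um at the face
  raw <- convert_box_params(23, 23, 5, 4, 11, scale = 73 / (2.7 * 30))
  expect_identical(raw, list(nx = 21L, ny = 21L, nrx = 5L, nry = 4L,
                             nc = 10L))
  bb <- measurement_box(c(326, 326), raw$nx, raw$ny, raw$nrx, raw$nry,
                        raw$nc)
  expect_identical(c(bb$M, bb$N), c(139L, 302L))
})

make_image <- function(m, origin = c(1L, 1L)) {
  structure(m, kind = "raw", exposure_s = 1, origin = origin,
            pixel_um = 73, class = "ptccd_image")
}

test_that("background plane fit recovers exact planes and matches lm", {
  box <- measurement_box(c(3, 3), 5, 5, 1, 1)
  img <- make_image(outer(1:5, 1:5, function(i, j) 2 * (i - 3) - (j - 3) + 7))
  pl <- fit_background_plane(img, box)
  expect_equal(c(pl$a, pl$b, pl$c), c(2, -1, 7), tolerance = 1e-12)
  # constant background
  img2 <- make_image(matrix(4.5, 5, 5))
  pl2 <- fit_background_plane(img2, box)
  expect_equal(c(pl2$a, pl2$b, pl2$c), c(0, 0, 4.5), tolerance = 1e-12)
  # noisy box against an independent lm() solve on the rim pixels
  set.seed(31)
  noisy <- matrix(rnorm(25, 10, 2), 5, 5)
  img3 <- make_image(noisy)
  pl3 <- fit_background_plane(img3, box)
  bg <- box$background
  ref <- lm(noisy[bg] ~ box$dx[bg] + box$dy[bg])
  expect_equal(pl3$a, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(pl3$b, unname(coef(ref)[3]), tolerance = 1e-10)
  expect_equal(pl3$c, unname(coef(ref)[1]), tolerance = 1e-10)
})

test_that("summation integration subtracts the fitted plane", {
  box <- measurement_box(c(3, 3), 5, 5, 1, 1)
  # pure plane: intensity zero
  img <- make_image(outer(1:5, 1:5, function(i, j) 3 * i + 2 * j + 1))
  expect_equal(summation_integrate(img, box)$intensity, 0,
               tolerance = 1e-10)
  # hand-computed example: 3x3 peak on a unit background
  peak <- rbind(c(1, 2, 1), c(2, 10, 2), c(1, 2, 1))
  m <- matrix(1, 5, 5)
  m[2:4, 2:4] <- peak + 1  # spot sits on the background level
  res <- summation_integrate(make_image(m), box)
  expect_equal(res$intensity, sum(peak), tolerance = 1e-10)  # 22 - 9 + 9... spot only
  # the quoted toy: rho = peak values, true plane (0,0,1)
  m2 <- matrix(1, 5, 5)
  m2[2:4, 2:4] <- peak
  res2 <- summation_integrate(make_image(m2), box)
  expect_equal(res2$intensity, 22 - 9, tolerance = 1e-10)
  # invariance: adding any plane changes nothing (plane is refit)
  set.seed(32)
  rnd <- matrix(rpois(25, 30), 5, 5)
  i0 <- summation_integrate(make_image(rnd), box)$intensity
  tilt <- outer(1:5, 1:5, function(i, j) -4 * i + 2.5 * j + 11)
  i1 <- summation_integrate(make_image(rnd + tilt), box)$intensity
  expect_equal(i0, i1, tolerance = 1e-9)
})

test_that("cascade estimator reduces to the Poisson estimator for an ideal counter", {
  # gamma = 1, psi = 0: the two error models agree on any box
  ideal <- noise_budget(ideal_params())
  expect_equal(ideal$gamma, 1)
  expect_equal(ideal$psi, 0)
  box <- measurement_box(c(12, 12), 23, 23, 5, 4, 11)
  set.seed(33)
  for (i in 1:5) {
    img <- make_image(matrix(rpois(23 * 23, 40), 23, 23) +
                        5 * (i - 3))
    res <- summation_integrate(img, box)
    vp <- variance_poisson_mosflm(res, ideal$gain_absorbed)
    vc <- variance_cascade(res, ideal, quiet = TRUE)
    expect_equal(vc, vp, tolerance = 1e-10)
  }
  # and the fallback emits a message when raw-pixel counts are missing
  img <- make_image(matrix(rpois(23 * 23, 40), 23, 23))
  res <- summation_integrate(img, box)
  expect_message(variance_cascade(res, ref_budget()), "approximating")
})

test_that("reference profile is the mean background-corrected box", {
  box <- measurement_box(c(3, 3), 5, 5, 1, 1)
  spot <- matrix(0, 5, 5); spot[2:4, 2:4] <- rbind(c(1, 2, 1), c(2, 9, 2),
                                                   c(1, 2, 1))
  img <- make_image(spot + 3)  # constant background 3
  prof <- build_reference_profile(list(img), box)
  expect_equal(prof, spot)
  # linear in the image scale, stable under replication
  prof2 <- build_reference_profile(list(img, img, img), box)
  expect_equal(prof2, prof)
})

test_that("profile fitting recovers a noiseless scale in both modes", {
  box <- measurement_box(c(4, 4), 7, 7, 2, 2)
  prof <- matrix(0, 7, 7)
  prof[3:5, 3:5] <- rbind(c(2, 5, 2), c(5, 20, 5), c(2, 5, 2))
  truth <- 3.25
  img <- make_image(truth * prof +
                      outer(1:7, 1:7, function(i, j) 0.5 * i - 0.2 * j + 6))
  res <- profile_fit(img, box, profile = prof)
  expect_equal(res$intensity, truth * sum(prof), tolerance = 1e-8)
  expect_equal(res$variance, 0, tolerance = 1e-6)
  sigma <- diag(49) + 0.2
  res2 <- profile_fit(img, box, profile = prof, weights = sigma)
  expect_equal(res2$intensity, truth * sum(prof), tolerance = 1e-6)
})

test_that("GLS variance estimate matches the true scatter under known covariance", {
  # correlated Gaussian pixels with known covariance: the GLS fit's
  # normal-equations variance must equal the observed variance of I_P
  set.seed(34)
  box <- measurement_box(c(4, 4), 7, 7, 2, 2)
  prof <- matrix(0, 7, 7)
  prof[3:5, 3:5] <- rbind(c(2, 5, 2), c(5, 20, 5), c(2, 5, 2))
  d2 <- as.matrix(dist(cbind(as.numeric(box$dx), as.numeric(box$dy))))
  sigma <- 9 * exp(-d2 / 2)
  R <- chol(sigma)
  fitter <- ptccd:::profile_fitter(box, prof, weights = sigma)
  X <- ptccd:::profile_design(box, prof)
  n_rep <- 4000
  ip <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    y <- as.numeric(X %*% c(2, 0.3, -0.2, 5)) +
      as.numeric(crossprod(R, rnorm(49)))
    ip[i] <- fitter(matrix(y, 7, 7))$intensity
  }
  est <- fitter(matrix(rnorm(49), 7, 7))$variance  # same for any input
  expect_equal(var(ip) / est, 1, tolerance = 0.1)
})

test_that("empirical covariance truncates at the lag and flags non-PSD input", {
  set.seed(35)
  box <- measurement_box(c(3, 3), 5, 5, 1, 1)
  rasters <- matrix(rnorm(400 * 25, 0, 3), 400, 25)
  cm <- empirical_pixel_covariance(rasters, box, max_lag = 1)
  expect_s3_class(cm, "covariance_model")
  # beyond-lag entries are exactly zero
  far <- abs(outer(as.numeric(box$dx), as.numeric(box$dx), `-`)) > 1 |
    abs(outer(as.numeric(box$dy), as.numeric(box$dy), `-`)) > 1
  expect_true(all(cm$sigma[far] == 0))
  # i.i.d. input: off-diagonals are small relative to the diagonal
  offd <- cm$sigma[!far & row(cm$sigma) != col(cm$sigma)]
  expect_lt(max(abs(offd)), 9 * 5 / sqrt(400))
  # non-PSD matrices are projected with a warning
  bad <- diag(25); bad[1, 2] <- bad[2, 1] <- 2
  prof <- matrix(0, 5, 5); prof[3, 3] <- 10
  expect_warning(profile_fit(make_image(matrix(rnorm(25), 5, 5)), box,
                             profile = prof, weights = bad),
                 "clipped")
})
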