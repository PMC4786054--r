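#' MOSFLM-style measurement box
#'
#' A rectangular box of `nx` x `ny` pixels around a spot, partitioned into a
#' peak region and a background region: rim pixels within `nrx` (`nry`) of
#' the vertical (horizontal) box edges belong to the background, and corner
#' pixels with `|dx| + |dy| > nc` are cut from the peak and assigned to the
#' background. Both side lengths must be odd so the box has a central pixel;
#' the resulting masks have mm symmetry.
#'
#' @param center length-2 integer vector, box centre pixel (1-based, on the
#'   grid of the image to be integrated).
#' @param nx,ny box side lengths in pixels (odd).
#' @param nrx,nry background rim widths in pixels (>= 0; rims must leave a
#'   non-empty peak).
#' @param nc corner cut-off: pixels with `|dx| + |dy| > nc` go to the
#'   background.
#' @return an object of class `measurement_box` with logical `peak` and
#'   `background` masks, pixel offset grids `dx`, `dy`, and counts `M`
#'   (peak) and `N` (background).
#' @export
#' @examples
#' b <- measurement_box(c(306, 306), 23, 23, 5, 4, 11)
#' c(b$M, b$N)  # 183 peak, 346 background pixels
measurement_box <- function(center, nx, ny, nrx = 0L, nry = 0L,
                            nc = nx + ny) {
  if (nx %% 2L != 1L || ny %% 2L != 1L)
    stop("'nx' and 'ny' must be odd", call. = FALSE)
  if (nrx < 0 || nry < 0) stop("rim widths must be >= 0", call. = FALSE)
  hx <- (nx - 1L) %/% 2L; hy <- (ny - 1L) %/% 2L
  if (nrx > hx || nry > hy)
    stop("rims leave no peak region", call. = FALSE)
  dx <- matrix(rep(-hx:hx, ny), nx, ny)
  dy <- matrix(rep(-hy:hy, each = nx), nx, ny)
  rim <- abs(dx) > hx - nrx | abs(dy) > hy - nry
  cut <- abs(dx) + abs(dy) > nc
  peak <- !rim & !cut
  if (!any(peak)) stop("corner cut leaves no peak region", call. = FALSE)
  structure(list(center = as.integer(center), nx = as.integer(nx),
                 ny = as.integer(ny), nrx = as.integer(nrx),
                 nry = as.integer(nry), nc = as.integer(nc),
                 dx = dx, dy = dy, peak = peak, background = !peak,
                 M = sum(peak), N = sum(!peak)),
            class = "measurement_box")
}

#' @export
print.measurement_box <- function(x, ...) {
  cat(sprintf(paste0("measurement box %dx%d at (%d, %d), rims (%d, %d), ",
                     "corner cut %d: M = %d peak, N = %d background px\n"),
              x$nx, x$ny, x$center[1L], x$center[2L], x$nrx, x$nry, x$nc,
              x$M, x$N))
  invisible(x)
}

#' Convert face-grid box parameters to another pixel pitch
#'
#' Box parameters are naturally quoted in corrected-image (face-grid, 73 um)
#' pixels. To integrate the same physical region on a raw image, whose
#' pixels subtend `demag * ccd_pixel_um` at the face, the parameters are
#' scaled by the pitch ratio; side lengths are rounded to the nearest odd
#' integer and rims and the corner cut to the nearest integer.
#'
#' @param nx,ny,nrx,nry,nc box parameters in face pixels.
#' @param scale pitch ratio (face pitch / target pitch at the face); 1 leaves
#'   the parameters untouched.
#' @return named list of converted parameters.
#' @export
#' @examples
#' convert_box_params(23, 23, 5, 4, 11, scale = 73 / (2.7 * 30))
convert_box_params <- function(nx, ny, nrx, nry, nc, scale = 1) {
  odd <- function(v) {
    o <- 2L * as.integer(round((v - 1) / 2)) + 1L
    max(o, 1L)
  }
  list(nx = odd(nx * scale), ny = odd(ny * scale),
       nrx = as.integer(round(nrx * scale)),
       nry = as.integer(round(nry * scale)),
       nc = as.integer(round(nc * scale)))
}

# extract the pedestal-subtracted box raster from an image (local window
# indexing via the image origin)
box_values <- function(image, box, pedestal = 0) {
  o <- attr(image, "origin")
  if (is.null(o)) o <- c(1L, 1L)
  hx <- (box$nx - 1L) %/% 2L; hy <- (box$ny - 1L) %/% 2L
  rows <- (box$center[1L] - hx):(box$center[1L] + hx) - o[1L] + 1L
  cols <- (box$center[2L] - hy):(box$center[2L] + hy) - o[2L] + 1L
  if (rows[1L] < 1L || cols[1L] < 1L ||
      rows[length(rows)] > nrow(image) || cols[length(cols)] > ncol(image))
    stop("measurement box does not fit inside the image window", call. = FALSE)
  unclass(image)[rows, cols] - pedestal
}

#' Fit the background plane of a measurement box
#'
#' Unweighted least-squares fit of a plane `a*dx + b*dy + c` to the
#' background-region pixels (Rossmann-style). Pixels have the pedestal
#' subtracted first; for mm-symmetric boxes the design is orthogonal, so `c`
#' is the background mean and `a`, `b` are the slopes.
#'
#' @param image a `ptccd_image` containing the box.
#' @param box a [measurement_box()].
#' @param pedestal pedestal/bias offset to subtract from pixel values before
#'   fitting.
#' @return an object of class `background_plane`: `a`, `b`, `c`, residual
#'   standard deviation `sigma`, and the pedestal used.
#' @export
fit_background_plane <- function(image, box, pedestal = 0) {
  rho <- box_values(image, box, pedestal)
  bg <- box$background
  if (sum(bg) < 3L) stop("need >= 3 background pixels", call. = FALSE)
  X <- cbind(box$dx[bg], box$dy[bg], 1)
  if (qr(X)$rank < 3L)
    stop("degenerate background geometry (collinear pixels)", call. = FALSE)
  fit <- stats::lm.fit(X, rho[bg])
  structure(list(a = fit$coefficients[[1L]], b = fit$coefficients[[2L]],
                 c = fit$coefficients[[3L]],
                 sigma = sqrt(sum(fit$residuals^2) /
                                max(1L, sum(bg) - 3L)),
                 pedestal = pedestal),
            class = "background_plane")
}

#' Summation integration of a spot
#'
#' Background-plane-subtracted sum over the peak region:
#' \deqn{I_S = \sum_{peak} \rho_i - \sum_{peak} (a p_i + b q_i + c).}
#'
#' @inheritParams fit_background_plane
#' @param plane a [fit_background_plane()] result for the same box (fitted
#'   here when `NULL`).
#' @return an object of class `integration_result` carrying the intensity,
#'   the peak and background region totals (pedestal-subtracted), region
#'   sizes and the plane.
#' @export
summation_integrate <- function(image, box, plane = NULL, pedestal = 0) {
  if (is.null(plane)) plane <- fit_background_plane(image, box, pedestal)
  rho <- box_values(image, box, plane$pedestal)
  pk <- box$peak
  bg_under_peak <- plane$a * box$dx[pk] + plane$b * box$dy[pk] + plane$c
  structure(list(intensity = sum(rho[pk]) - sum(bg_under_peak),
                 peak_total = sum(rho[pk]),
                 bg_total = sum(rho[box$background]),
                 M = box$M, N = box$N, plane = plane,
                 method = "summation"),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("%s integration: I = %.1f ADU (M = %d, N = %d)\n",
              x$method, x$intensity, x$M, x$N))
  if (!is.null(x$variance))
    cat(sprintf("  estimated variance %.1f ADU^2\n", x$variance))
  invisible(x)
}

#' Independent-Poisson-pixel variance of a summation intensity
#'
#' The classical estimate assuming every pixel is an independent Poisson
#' counter with gain `G`:
#' \deqn{\sigma^2(I_S) = G\,[\,I_S + I_{bg}(1 + M/N)\,],}
#' with `I_bg = (M/N) * sum(background)` the interpolated background under
#' the peak.
#'
#' @param result a summation [integration_result].
#' @param gain_absorbed absorbed-photon gain G, ADU/photon.
#' @return variance in ADU^2.
#' @export
variance_poisson_mosflm <- function(result, gain_absorbed) {
  i_bg <- result$M / result$N * result$bg_total
  gain_absorbed * (result$intensity + i_bg * (1 + result$M / result$N))
}

#' Cascade-model variance of a summation intensity
#'
#' Applies the cascade + pixel noise region-sum variance to the peak total
#' and (via the mm-symmetry background simplification) to the background
#' term:
#' \deqn{\sigma^2(I_S) = [\gamma G P_{peak} + M_{raw}\psi] +
#'   (M/N)^2 [\gamma G P_{bg} + N_{raw}\psi],}
#' where `P_peak` and `P_bg` are the pedestal-corrected region totals. The
#' raw-image pixel counts behind the regions default to the corrected-box
#' counts `M` and `N` (a slight overestimate for corrected images); exact
#' effective counts can be supplied from [effective_raw_pixels()].
#'
#' @param result a summation [integration_result].
#' @param budget a [noise_budget()].
#' @param n_raw_pixels_peak,n_raw_pixels_bg raw-pixel counts behind the peak
#'   and background regions; `NULL` falls back to `M` and `N` with a
#'   message.
#' @param quiet suppress the fallback message.
#' @return variance in ADU^2.
#' @export
variance_cascade <- function(result, budget, n_raw_pixels_peak = NULL,
                             n_raw_pixels_bg = NULL, quiet = FALSE) {
  stopifnot(inherits(budget, "noise_budget"))
  if (is.null(n_raw_pixels_peak) || is.null(n_raw_pixels_bg)) {
    if (!quiet)
      message("raw-pixel counts not supplied; approximating by the ",
              "measurement-box pixel counts")
    n_raw_pixels_peak <- result$M
    n_raw_pixels_bg <- result$N
  }
  gG <- budget$gamma * budget$gain_absorbed
  (gG * result$peak_total + n_raw_pixels_peak * budget$psi) +
    (result$M / result$N)^2 *
    (gG * result$bg_total + n_raw_pixels_bg * budget$psi)
}

#' Build a reference spot profile from replicate images
#'
#' Mean of the pedestal- and background-plane-corrected measurement boxes of
#' a set of replicate spot images, rounded to the nearest ADU.
#'
#' @param images list of `ptccd_image`s containing the box.
#' @param box a [measurement_box()].
#' @param pedestal pedestal offset of the images.
#' @return numeric `nx x ny` profile raster (integer-valued).
#' @export
build_reference_profile <- function(images, box, pedestal = 0) {
  stopifnot(length(images) >= 1L)
  acc <- matrix(0, box$nx, box$ny)
  for (im in images) {
    pl <- fit_background_plane(im, box, pedestal)
    rho <- box_values(im, box, pedestal)
    acc <- acc + rho - (pl$a * box$dx + pl$b * box$dy + pl$c)
  }
  round(acc / length(images))
}

#' Empirical pixel variance-covariance model for a box footprint
#'
#' Unbiased sample variances and covariances of the box pixels over an
#' ensemble of replicate rasters, truncated to zero beyond a maximum lag in
#' X and Y (correlations from the point spread and the distortion correction
#' are short-ranged).
#'
#' @param rasters matrix with one row per replicate and one column per box
#'   pixel (column-major box order), or a list of box rasters.
#' @param box the [measurement_box()] the rasters belong to.
#' @param max_lag covariances with `|dx| > max_lag` or `|dy| > max_lag` are
#'   set to zero.
#' @return an object of class `covariance_model`: the `nx*ny` square matrix
#'   `sigma`, plus `max_lag` and the box dimensions.
#' @export
empirical_pixel_covariance <- function(rasters, box, max_lag = 7L) {
  if (is.list(rasters))
    rasters <- do.call(rbind, lapply(rasters, as.numeric))
  stopifnot(nrow(rasters) >= 2L, ncol(rasters) == box$nx * box$ny)
  sigma <- stats::cov(rasters)
  ix <- as.numeric(box$dx); iy <- as.numeric(box$dy)
  keep <- abs(outer(ix, ix, `-`)) <= max_lag &
    abs(outer(iy, iy, `-`)) <= max_lag
  sigma[!keep] <- 0
  structure(list(sigma = sigma, max_lag = as.integer(max_lag),
                 nx = box$nx, ny = box$ny, n = nrow(rasters)),
            class = "covariance_model")
}

# design matrix for the joint profile + plane fit over the whole box
profile_design <- function(box, profile) {
  cbind(K = as.numeric(profile), a = as.numeric(box$dx),
        b = as.numeric(box$dy), c = 1)
}

# ensure a symmetric matrix is usable as a covariance: clip non-positive
# eigenvalues, preserving the diagonal scale
project_psd <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (all(e$values > 0)) return(list(sigma = sigma, projected = FALSE))
  floor_ev <- 1e-8 * max(e$values)
  v <- pmax(e$values, floor_ev)
  list(sigma = e$vectors %*% (v * t(e$vectors)), projected = TRUE)
}

#' Profile-fitting integration
#'
#' Fits the reference profile and a background plane jointly to the
#' measurement box by (generalized) least squares,
#' `rho_i = K * phi_i + a p_i + b q_i + c`, and reports the intensity
#' `I_P = K * sum(phi)` with its variance from the fit.
#'
#' Two weighting modes:
#' \describe{
#'   \item{diagonal}{independent-Poisson pixel weights `1/mu_i` (expected
#'     values from the profile and plane; the absolute scale cancels). The
#'     variance is the residual-scaled weighted-least-squares covariance,
#'     i.e. the "quality of fit" estimate — which underestimates the true
#'     scatter when pixels are correlated.}
#'   \item{covariance}{generalized least squares with a full pixel
#'     variance-covariance matrix (a [covariance_model] or matrix), giving
#'     `Var(K) = [(X' M^-1 X)^-1]_KK` with no residual scaling. A non-PSD
#'     empirical matrix is eigenvalue-clipped with a warning.}
#' }
#'
#' @inheritParams summation_integrate
#' @param profile reference profile raster from [build_reference_profile()].
#' @param weights `"diagonal"`, or a [covariance_model] / square matrix for
#'   GLS.
#' @return an [integration_result] with `intensity`, `variance` and the
#'   fitted coefficients.
#' @export
profile_fit <- function(image, box, plane = NULL, profile,
                        weights = "diagonal", pedestal = 0) {
  if (is.null(plane)) plane <- fit_background_plane(image, box, pedestal)
  fitter <- profile_fitter(box, profile, weights,
                           bg_level = max(plane$c, 1))
  rho <- box_values(image, box, plane$pedestal)
  fitter(rho)
}

# precomputes the fit operators for repeated use on one geometry; returns a
# closure mapping a box raster to an integration_result
profile_fitter <- function(box, profile, weights = "diagonal", bg_level = 1) {
  X <- profile_design(box, profile)
  phi_sum <- sum(profile)
  n <- nrow(X)
  if (identical(weights, "diagonal")) {
    # independent-Poisson expected-value weights: profile shape on top of a
    # flat background level; the absolute scale cancels in the
    # residual-scaled variance
    mu0 <- pmax(as.numeric(profile), 0) + max(bg_level, 1)
    W <- 1 / mu0
    XtW <- t(X * W)
    A <- XtW %*% X
    Ainv <- solve(A)
    H <- Ainv %*% XtW        # coefficients = H %*% rho
    function(rho) {
      y <- as.numeric(rho)
      beta <- as.numeric(H %*% y)
      r <- y - as.numeric(X %*% beta)
      s2 <- sum(W * r^2) / (n - 4L)
      structure(list(intensity = beta[1L] * phi_sum,
                     variance = phi_sum^2 * s2 * Ainv[1L, 1L],
                     coefficients = beta, scale = s2,
                     M = box$M, N = box$N, method = "profile"),
                class = "integration_result")
    }
  } else {
    sigma <- if (inherits(weights, "covariance_model")) weights$sigma
             else as.matrix(weights)
    stopifnot(nrow(sigma) == n, ncol(sigma) == n)
    pr <- project_psd(sigma)
    if (pr$projected)
      warning("covariance model is not positive definite; ",
              "eigenvalues clipped")
    R <- chol(pr$sigma + diag(1e-10 * mean(diag(pr$sigma)), n))
    Xs <- backsolve(R, X, transpose = TRUE)
    A <- crossprod(Xs)
    Ainv <- solve(A)
    function(rho) {
      y <- backsolve(R, as.numeric(rho), transpose = TRUE)
      beta <- as.numeric(Ainv %*% crossprod(Xs, y))
      structure(list(intensity = beta[1L] * phi_sum,
                     variance = phi_sum^2 * Ainv[1L, 1L],
                     coefficients = beta, scale = 1,
                     M = box$M, N = box$N, method = "profile-gls"),
                class = "integration_result")
    }
  }
}
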