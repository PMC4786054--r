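#' Clip a convex polygon against an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of the rectangle.
#' Used to compute the overlap areas that drive distortion correction.
#'
#' @param px,py polygon vertex coordinates (convex, in order).
#' @param xlo,xhi,ylo,yhi rectangle bounds.
#' @return list with vertex vectors `x`, `y` of the clipped polygon (possibly
#'   empty).
#' @keywords internal
clip_polygon_rect <- function(px, py, xlo, xhi, ylo, yhi) {
  clip_edge <- function(x, y, inside) {
    n <- length(x)
    if (n == 0L) return(list(x = x, y = y))
    keep <- inside(x, y)
    ox <- numeric(0); oy <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (keep[i]) { ox <- c(ox, x[i]); oy <- c(oy, y[i]) }
      if (keep[i] != keep[j]) {
        # intersection with the clip line (one coordinate is constant)
        t <- attr(inside, "t")(x[i], y[i], x[j], y[j])
        ox <- c(ox, x[i] + t * (x[j] - x[i]))
        oy <- c(oy, y[i] + t * (y[j] - y[i]))
      }
    }
    list(x = ox, y = oy)
  }
  mk <- function(test, tfun) { attr(test, "t") <- tfun; test }
  edges <- list(
    mk(function(x, y) x >= xlo, function(x1, y1, x2, y2) (xlo - x1) / (x2 - x1)),
    mk(function(x, y) x <= xhi, function(x1, y1, x2, y2) (xhi - x1) / (x2 - x1)),
    mk(function(x, y) y >= ylo, function(x1, y1, x2, y2) (ylo - y1) / (y2 - y1)),
    mk(function(x, y) y <= yhi, function(x1, y1, x2, y2) (yhi - y1) / (y2 - y1)))
  p <- list(x = px, y = py)
  for (e in edges) p <- clip_edge(p$x, p$y, e)
  p
}

# shoelace area of a polygon given in order
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Build the distortion map for a raw-pixel window
#'
#' Maps the corners of each CCD pixel back along the taper to the detector
#' face, forming one quadrilateral per raw pixel, and records each quad's
#' face area as an effective-collection-area factor (relative to the 73 um
#' face pixel area). The quads are convex for the monotone radial distortions
#' used here; degenerate (zero-area) quads are rejected.
#'
#' @param taper a [taper_model()].
#' @param window list with `x`, `y` integer ranges of raw (CCD) pixels;
#'   default full frame.
#' @return an object of class `distortion_map`: vertex arrays, per-pixel
#'   `area_factor` matrix, and the window.
#' @export
build_distortion_map <- function(taper, window = NULL) {
  stopifnot(inherits(taper, "taper_model"))
  if (is.null(window))
    window <- list(x = c(1L, taper$n_ccd), y = c(1L, taper$n_ccd))
  xs <- (window$x[1L] - 1L):window$x[2L] * taper$ccd_pixel_um
  ys <- (window$y[1L] - 1L):window$y[2L] * taper$ccd_pixel_um
  corners <- as.matrix(expand.grid(x = xs, y = ys))
  face <- ccd_to_face(corners, taper)
  nvx <- length(xs)
  vx <- matrix(face[, 1L], nvx)
  vy <- matrix(face[, 2L], nvx)
  nx <- nvx - 1L; ny <- ncol(vx) - 1L
  # quad area via the shoelace formula on the 4 mapped corners
  i <- seq_len(nx); j <- seq_len(ny)
  x00 <- vx[i, j]; y00 <- vy[i, j]
  x10 <- vx[i + 1L, j]; y10 <- vy[i + 1L, j]
  x11 <- vx[i + 1L, j + 1L]; y11 <- vy[i + 1L, j + 1L]
  x01 <- vx[i, j + 1L]; y01 <- vy[i, j + 1L]
  area <- abs((x00 * y10 - x10 * y00) + (x10 * y11 - x11 * y10) +
                (x11 * y01 - x01 * y11) + (x01 * y00 - x00 * y01)) / 2
  if (any(area <= 0))
    stop("degenerate (zero-area) pixel quadrilateral in distortion map",
         call. = FALSE)
  structure(list(taper = taper, window = window,
                 vx = vx, vy = vy,
                 area_um2 = area,
                 area_factor = area / taper$face_pixel_um^2),
            class = "distortion_map")
}

#' Redistribution operator from raw quads onto the orthogonal face grid
#'
#' For every raw pixel in the map's window, clips its face quadrilateral
#' against the 73 um cells of a target corrected window and splits the
#' pixel's value between those cells in proportion to the clipped areas.
#' Total value is conserved up to the fraction of quad area falling outside
#' the target window, which is recorded.
#'
#' @param map a [build_distortion_map()] result.
#' @param corrected_window list with `x`, `y` integer ranges of target face
#'   pixels; default the full face grid.
#' @return a sparse `dgCMatrix` of dimension (target pixels) x (raw pixels),
#'   column `i` holding the area fractions of raw pixel `i`; attribute
#'   `out_fraction` gives each raw pixel's area fraction outside the target
#'   window.
#' @export
redistribution_matrix <- function(map, corrected_window = NULL) {
  stopifnot(inherits(map, "distortion_map"))
  tp <- map$taper
  if (is.null(corrected_window))
    corrected_window <- list(x = c(1L, tp$n_face), y = c(1L, tp$n_face))
  p <- tp$face_pixel_um
  cx0 <- corrected_window$x[1L]; cx1 <- corrected_window$x[2L]
  cy0 <- corrected_window$y[1L]; cy1 <- corrected_window$y[2L]
  ntx <- cx1 - cx0 + 1L; nty <- cy1 - cy0 + 1L
  nx <- nrow(map$area_um2); ny <- ncol(map$area_um2)
  ti <- vector("list", nx * ny); tj <- ti; tv <- ti
  out_fraction <- matrix(0, nx, ny)
  for (jj in seq_len(ny)) {
    for (ii in seq_len(nx)) {
      qx <- c(map$vx[ii, jj], map$vx[ii + 1L, jj],
              map$vx[ii + 1L, jj + 1L], map$vx[ii, jj + 1L])
      qy <- c(map$vy[ii, jj], map$vy[ii + 1L, jj],
              map$vy[ii + 1L, jj + 1L], map$vy[ii, jj + 1L])
      a <- map$area_um2[ii, jj]
      # candidate target cells from the quad bounding box
      fx <- max(floor(min(qx) / p) + 1L, cx0):min(floor(max(qx) / p) + 1L, cx1)
      fy <- max(floor(min(qy) / p) + 1L, cy0):min(floor(max(qy) / p) + 1L, cy1)
      if (fx[1L] > fx[length(fx)] || fy[1L] > fy[length(fy)]) {
        out_fraction[ii, jj] <- 1
        next
      }
      raw_idx <- ii + nx * (jj - 1L)
      covered <- 0
      k <- 0L
      is <- integer(length(fx) * length(fy)); vs <- numeric(length(is))
      for (cy in fy) {
        for (cx in fx) {
          cl <- clip_polygon_rect(qx, qy, (cx - 1) * p, cx * p,
                                  (cy - 1) * p, cy * p)
          ov <- polygon_area(cl$x, cl$y)
          if (ov > 0) {
            k <- k + 1L
            is[k] <- (cx - cx0 + 1L) + ntx * (cy - cy0)
            vs[k] <- ov / a
            covered <- covered + ov / a
          }
        }
      }
      if (k > 0L) {
        ti[[raw_idx]] <- is[seq_len(k)]
        tv[[raw_idx]] <- vs[seq_len(k)]
        tj[[raw_idx]] <- rep.int(raw_idx, k)
      }
      out_fraction[ii, jj] <- max(0, 1 - covered)
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                            dims = c(ntx * nty, nx * ny))
  attr(S, "out_fraction") <- out_fraction
  attr(S, "corrected_window") <- corrected_window
  S
}

#' Reapportion raw-pixel values onto the orthogonal face grid
#'
#' @param values numeric matrix of raw-pixel values matching the map window.
#' @param map a [build_distortion_map()] result.
#' @param S optional precomputed [redistribution_matrix()] (built on the fly
#'   otherwise).
#' @param corrected_window target face-pixel window (used when `S` is built
#'   here).
#' @return numeric matrix of redistributed values on the target window, with
#'   attribute `lost` (total value that fell outside the window).
#' @export
polygon_overlap_redistribute <- function(values, map, S = NULL,
                                         corrected_window = NULL) {
  if (is.null(S)) S <- redistribution_matrix(map, corrected_window)
  w <- attr(S, "corrected_window")
  v <- as.numeric(S %*% as.numeric(values))
  out <- matrix(v, w$x[2L] - w$x[1L] + 1L, w$y[2L] - w$y[1L] + 1L)
  attr(out, "lost") <- sum(as.numeric(values) *
                             as.numeric(attr(S, "out_fraction")))
  out
}

#' Build a master dark image
#'
#' Average of `n_images` dark exposures (no beam). The read-noise standard
#' deviation of the average falls as `sigma_r / sqrt(n)`; the average also
#' carries the ADC bias and the (tiny) accumulated dark signal, so
#' subtracting it removes both from raw images.
#'
#' @param config a [detector_config()]; ignored when `images` is supplied.
#' @param exposure_s exposure length of each dark, seconds.
#' @param n_images number of dark exposures to average (>= 1).
#' @param window raw-pixel window (default full frame).
#' @param seed optional integer seed.
#' @param images optional list of dark `ptccd_image`s to average instead of
#'   simulating; all must share one exposure length.
#' @return a numeric matrix of class `ptccd_dark` with attribute
#'   `exposure_s`.
#' @export
build_dark <- function(config, exposure_s = 1, n_images = 200L,
                       window = NULL, seed = NULL, images = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(images)) {
    stopifnot(inherits(config, "detector_config"), n_images >= 1)
    none <- list(xy = matrix(numeric(0), 0L, 2L))
    images <- replicate(n_images,
                        ccd_expose(none, exposure_s, config, window = window,
                                   kind = "dark"),
                        simplify = FALSE)
  }
  exps <- vapply(images, function(im) attr(im, "exposure_s"), 0)
  if (length(unique(exps)) != 1L)
    stop("dark images have mixed exposure lengths", call. = FALSE)
  acc <- Reduce(`+`, lapply(images, unclass)) / length(images)
  structure(acc, exposure_s = exps[1L],
            origin = attr(images[[1L]], "origin"), class = "ptccd_dark")
}

#' Build a flat-field normalization array
#'
#' Averages dark-corrected flood images, divides by each raw pixel's
#' effective collection area at the detector face (the taper distortion is
#' non-area preserving, so even a perfectly uniform flood shows a density
#' gradient across raw pixels), and normalizes to mean 1. The resulting
#' factors express how much each pixel responds above or below the uniform
#' expectation.
#'
#' @param floods list of flood `ptccd_image`s (same window and exposure).
#' @param dark a [build_dark()] result matching the window.
#' @param map a [build_distortion_map()] for the same window (provides the
#'   area factors).
#' @return a numeric matrix of class `flat_field`, mean 1, all entries > 0.
#' @export
build_flat_field <- function(floods, dark, map) {
  stopifnot(length(floods) >= 1L, inherits(map, "distortion_map"))
  exps <- vapply(floods, function(im) attr(im, "exposure_s"), 0)
  if (length(unique(exps)) != 1L)
    stop("flood images have mixed exposure lengths", call. = FALSE)
  avg <- Reduce(`+`, lapply(floods, unclass)) / length(floods) - unclass(dark)
  scaled <- avg / map$area_factor
  if (any(scaled <= 0))
    stop("non-positive averaged flood value after dark correction; ",
         "increase flood counts", call. = FALSE)
  structure(scaled / mean(scaled), class = "flat_field")
}

#' Apply the correction chain to a raw image
#'
#' Dark subtraction (removes bias and dark signal), then flat-field division,
#' then distortion correction by polygon-overlap reapportioning onto the
#' orthogonal 73 um face grid. A pedestal offset is re-added for storage and
#' recorded. Each stage is optional but later stages require the earlier
#' ones (a corrected image is always dark-subtracted, and
#' distortion-corrected implies flat-fielded when a flat is in use).
#'
#' @param raw a raw `ptccd_image`.
#' @param dark a [build_dark()] matching the raw window.
#' @param flat optional [build_flat_field()] matching the raw window.
#' @param map optional [build_distortion_map()]; when given (with `S` or
#'   built on the fly) the image is reapportioned onto the face grid.
#' @param S optional precomputed [redistribution_matrix()] for `map`.
#' @param corrected_window target face window when `S` is built here.
#' @param pedestal_adu pedestal re-added for storage.
#' @param quantize round to integer ADU for storage (default `TRUE`; the
#'   full-precision values are what integration sees when `FALSE`).
#' @return a `ptccd_image` of kind `"corrected"` with attributes `pedestal`,
#'   `corrections` (named logical vector) and `lost` (signal fallen outside
#'   the corrected window).
#' @export
correct_image <- function(raw, dark, flat = NULL, map = NULL, S = NULL,
                          corrected_window = NULL, pedestal_adu = 10,
                          quantize = TRUE) {
  stopifnot(inherits(raw, "ptccd_image"))
  if (!identical(dim(unclass(raw)), dim(unclass(dark))))
    stop("raw and dark image shapes differ", call. = FALSE)
  v <- unclass(raw) - unclass(dark)
  if (!is.null(flat)) {
    if (!identical(dim(v), dim(unclass(flat))))
      stop("flat-field shape differs from image", call. = FALSE)
    v <- v / unclass(flat)
  }
  lost <- 0
  pixel_um <- attr(raw, "pixel_um")
  origin <- attr(raw, "origin")
  distorted <- !is.null(map) || !is.null(S)
  if (distorted) {
    if (is.null(S)) S <- redistribution_matrix(map, corrected_window)
    v <- polygon_overlap_redistribute(v, map, S = S)
    lost <- attr(v, "lost")
    cw <- attr(S, "corrected_window")
    origin <- c(cw$x[1L], cw$y[1L])
    pixel_um <- if (!is.null(map)) map$taper$face_pixel_um else 73
  }
  v <- v + pedestal_adu
  if (quantize) v <- pmin(pmax(round(v), 0), 65535)
  structure(v,
            kind = "corrected", exposure_s = attr(raw, "exposure_s"),
            origin = origin, pixel_um = pixel_um,
            pedestal = pedestal_adu, lost = lost,
            corrections = c(dark = TRUE, flat = !is.null(flat),
                            distortion = distorted),
            seed = attr(raw, "seed"),
            class = "ptccd_image")
}

#' Effective raw-pixel count behind a corrected region
#'
#' The read-out and digitization noise entering a corrected-image region sum
#' is `sum_i w_i^2 * psi`, where `w_i` is the fraction of raw pixel `i`'s
#' value apportioned into the region. This returns `sum_i w_i^2` (the exact
#' effective pixel count computed from the distortion map) along with the
#' count of contributing raw pixels; approximating it by the number of
#' corrected pixels in the region slightly overestimates the noise.
#'
#' @param S a [redistribution_matrix()].
#' @param region_idx integer indices of target (corrected-window) pixels in
#'   the region.
#' @return named vector `c(effective, contributing)`.
#' @export
effective_raw_pixels <- function(S, region_idx) {
  w <- Matrix::colSums(S[region_idx, , drop = FALSE])
  c(effective = sum(w^2), contributing = sum(w > 0))
}
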