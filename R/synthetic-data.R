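#' Specification of a spherical vessel phantom
#'
#' Describes dark tubular "vessels" on a bright background, drawn on the
#' spherical chart of the retina and imaged through the schematic eye. Used
#' to test every stage of the pipeline with known ground truth.
#'
#' @param centerlines list of two-column matrices `(x, y)` of chart samples;
#'   each must stay within the retinal field of view `|x|, |y| <= 0.63`.
#' @param tube_width angular half-width of the Gaussian tube profile,
#'   radians.
#' @param contrast intensity drop at the tube center, in `[0, 1]`
#'   (background is 1, centerline is `1 - contrast`).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param image_size flat image side length in pixels.
#' @param seed_rng integer seed for the noise generator.
#' @return an object of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(centerlines, tube_width = 0.03, contrast = 0.7,
                                noise_sigma = 0.01, image_size = 128L,
                                seed_rng = 0L) {
  stopifnot(is.list(centerlines), tube_width > 0, contrast >= 0, contrast <= 1,
            noise_sigma >= 0, image_size >= 32)
  for (cl in centerlines) {
    stopifnot(is.matrix(cl), ncol(cl) == 2)
    if (max(abs(cl)) > 0.63 + 1e-9)
      stop("centerlines must stay within |x|, |y| <= 0.63", call. = FALSE)
  }
  structure(list(centerlines = centerlines, tube_width = tube_width,
                 contrast = contrast, noise_sigma = noise_sigma,
                 image_size = as.integer(image_size),
                 seed_rng = as.integer(seed_rng)),
            class = "vessel_phantom_spec")
}

#' Render a vessel phantom as a flat camera image
#'
#' Draws each centerline on the sphere with a smooth Gaussian cross-section
#' (angular distance to the supersampled centerline), projects the spherical
#' intensity to the flat image through the schematic eye, and adds seeded
#' Gaussian noise. Identical seeds give bit-identical images.
#'
#' @param spec a [vessel_phantom_spec()].
#' @param cam a [camera_model()].
#' @param XYlim half-extent of the flat raster; defaults to the projection
#'   of the field-of-view corner.
#' @return list with `image` (matrix, rows = Y), `centerlines_chart` (the
#'   input centerlines, supersampled), `centerlines_flat` (their projections
#'   in pixel coordinates `(row, col)`), `XYlim`.
#' @export
make_phantom <- function(spec, cam = camera_model(), XYlim = NULL) {
  np <- spec$image_size
  if (is.null(XYlim)) XYlim <- max(abs(retina_project(cam, 0.63, 0.63)))
  Xs <- seq(-XYlim, XYlim, length.out = np)
  Ys <- seq(-XYlim, XYlim, length.out = np)
  gr <- expand.grid(row = seq_len(np), col = seq_len(np))
  xy <- retina_unproject(cam, Xs[gr$col], Ys[gr$row])
  npix <- cbind(cos(xy[, 1]) * cos(xy[, 2]),
                cos(xy[, 1]) * sin(xy[, 2]),
                sin(xy[, 1]))
  img <- rep(1, nrow(npix))
  super <- lapply(spec$centerlines, function(cl) supersample_centerline(cl, np))
  for (cl in super) {
    ncl <- cbind(cos(cl[, 1]) * cos(cl[, 2]),
                 cos(cl[, 1]) * sin(cl[, 2]),
                 sin(cl[, 1]))
    # angular distance from each pixel to the nearest centerline sample,
    # chunked to bound memory
    dmax <- rep(-1, nrow(npix))
    for (i0 in seq(1, nrow(ncl), by = 256)) {
      i1 <- min(i0 + 255, nrow(ncl))
      m <- npix %*% t(ncl[i0:i1, , drop = FALSE])
      for (j in seq_len(ncol(m))) dmax <- pmax(dmax, m[, j])
    }
    dmin <- acos(pmin(1, pmax(-1, dmax)))
    img <- pmin(img, 1 - spec$contrast * exp(-dmin^2 / (2 * spec$tube_width^2)))
  }
  img <- matrix(img, np, np)
  if (spec$noise_sigma > 0) {
    rng <- get_rng_state()
    on.exit(restore_rng_state(rng))
    set.seed(spec$seed_rng)
    img <- img + matrix(stats::rnorm(np * np, sd = spec$noise_sigma), np, np)
  }
  flat <- lapply(super, function(cl) {
    XY <- retina_project(cam, cl[, 1], cl[, 2])
    cbind(row = (XY[, 2] + XYlim) / (2 * XYlim) * (np - 1) + 1,
          col = (XY[, 1] + XYlim) / (2 * XYlim) * (np - 1) + 1)
  })
  list(image = img, centerlines_chart = super, centerlines_flat = flat,
       XYlim = XYlim)
}

# supersample a polyline 4x relative to the pixel pitch
supersample_centerline <- function(cl, np) {
  seg <- sqrt(rowSums(diff(cl)^2))
  arc <- c(0, cumsum(seg))
  n_out <- max(nrow(cl), ceiling(arc[length(arc)] / (1.26 / np) * 4))
  ss <- seq(0, arc[length(arc)], length.out = n_out)
  cbind(stats::approx(arc, cl[, 1], xout = ss)$y,
        stats::approx(arc, cl[, 2], xout = ss)$y)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' S-shaped tube phantom
#'
#' Convenience phantom: a single serpentine vessel
#' `x(y) = amp * sin(freq * y)` across the field of view.
#'
#' @param amp amplitude of the serpentine in radians.
#' @param freq angular frequency. The default serpentine has peak geodesic
#'   curvature `amp * freq^2 ~ 1.4`, within the range observed for retinal
#'   vessels; its Gaussian cross-section (sigma = `tube_width`) matches the
#'   vesselness filter's scale range at the default image resolution.
#' @param y_range longitude range covered.
#' @param ... passed to [vessel_phantom_spec()].
#' @return a [vessel_phantom_spec()].
#' @export
s_tube_spec <- function(amp = 0.15, freq = 3, y_range = c(-0.5, 0.5), ...) {
  yy <- seq(y_range[1], y_range[2], length.out = 200)
  vessel_phantom_spec(list(cbind(amp * sin(freq * yy), yy)), ...)
}

#' Tabulate an exact cuspless geodesic as a regression fixture
#'
#' High-precision table of a cuspless geodesic (chart coordinates and
#' momenta against spherical arclength), for use as a frozen regression
#' fixture; values are reproducible to 12 significant digits.
#'
#' @param xi stiffness.
#' @param h2_0,h3_0 initial momenta, `|h2_0| < 1`.
#' @param s_end final spherical arclength, at most the first-cusp arclength.
#' @param n number of samples.
#' @return tibble with columns `s`, `x`, `y`, `theta`, `h1`, `h2`, `h3`.
#' @export
make_geodesic_fixture <- function(xi, h2_0, h3_0, s_end, n = 50) {
  params <- model_params(xi)
  smax <- cusp_arclength_smax(h2_0, h3_0, params)
  if (s_end > smax + 1e-12)
    stop(sprintf("s_end exceeds the first-cusp arclength %.6g", smax), call. = FALSE)
  ss <- seq(0, s_end, length.out = n)
  path <- cuspless_geodesic_s(h2_0, h3_0, params, ss)
  tibble::tibble(s = path$param, x = path$x, y = path$y, theta = path$theta,
                 h1 = path$h1, h2 = path$h2, h3 = path$h3)
}
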