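#' Specification of a synthetic fiber image
#'
#' Parameters of the synthetic fluorescent-fiber image generator, which
#' emulates labeled collagen fibers as anti-aliased line segments on a
#' noisy background. Images are grayscale matrices; pixel `[1, 1]` is the
#' top-left corner, and physical coordinates (micrometres) have the origin
#' at the image's lower-left corner with y pointing up.
#'
#' @param size Image side in pixels.
#' @param pixel_size Micrometres per pixel (default 1 for arithmetic
#'   transparency; the microscope scale is a free parameter).
#' @param n_fibers Number of fibers drawn.
#' @param fiber_length_mean,fiber_length_sd Fiber length distribution
#'   (normal, truncated at 5 um); default mean 47.5 um, the rigid-rod
#'   length.
#' @param fiber_width Fiber width in pixels (anti-aliased).
#' @param kappa Axial angular jitter: concentration of the doubled-angle
#'   von Mises distribution added to the local field angle (`0` =
#'   isotropic).
#' @param amplitude Peak fiber intensity.
#' @param background Constant background level.
#' @param noise `"gaussian"`, `"poisson"` or `"none"`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param poisson_scale Photons per intensity unit for Poisson noise.
#' @param psf_sigma Gaussian point-spread-function sigma, pixels.
#' @return An `image_spec` list.
#' @export
image_spec <- function(size = 512, pixel_size = 1, n_fibers = 800,
                       fiber_length_mean = 47.5, fiber_length_sd = 10,
                       fiber_width = 2, kappa = 8, amplitude = 1,
                       background = 0.05,
                       noise = c("gaussian", "poisson", "none"),
                       noise_sd = 0.02, poisson_scale = 200, psf_sigma = 1) {
  noise <- rlang::arg_match(noise)
  stopifnot(size >= 8, pixel_size > 0, n_fibers >= 0,
            fiber_length_mean >= pixel_size, kappa >= 0)
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_fibers = as.integer(n_fibers),
                 fiber_length_mean = fiber_length_mean,
                 fiber_length_sd = fiber_length_sd,
                 fiber_width = fiber_width, kappa = kappa,
                 amplitude = amplitude, background = background,
                 noise = noise, noise_sd = noise_sd,
                 poisson_scale = poisson_scale, psf_sigma = psf_sigma),
            class = "image_spec")
}

# physical (x, y) of pixel centers; origin = physical coords of lower-left
# image corner
pixel_centers <- function(nrow_px, ncol_px, pixel_size, origin = c(0, 0)) {
  list(x = function(col) origin[1] + (col - 0.5) * pixel_size,
       y = function(row) origin[2] + (nrow_px - row + 0.5) * pixel_size,
       row = function(y) nrow_px - (y - origin[2]) / pixel_size + 0.5,
       col = function(x) (x - origin[1]) / pixel_size + 0.5)
}

#' Render a synthetic fiber image with known ground truth
#'
#' Draws fibers as anti-aliased line segments whose axial angle is the local
#' field angle plus von Mises jitter, applies a Gaussian PSF and noise, and
#' returns the image together with the ground-truth fiber table. Fiber
#' centers are uniform over the canvas; segments extending beyond it are
#' clipped. Bit-reproducible given `(field, spec, seed)`.
#'
#' @param field An `orientation_grid`, or a single number: a global axial
#'   angle in degrees.
#' @param spec An [image_spec()].
#' @param seed RNG seed.
#' @param origin Physical coordinates (um) of the image's lower-left
#'   corner; aligns the canvas with the field's coordinate frame.
#' @return A list with `image` (numeric matrix in `[0, ~1]`) and `truth`
#'   (tibble `fiber`, `x`, `y`, `theta`, `length`: centers in um, axial
#'   angles in degrees).
#' @export
render_fiber_image <- function(field, spec = image_spec(), seed = 1,
                               origin = c(0, 0)) {
  stopifnot(inherits(spec, "image_spec"))
  n_px <- spec$size
  img <- matrix(0, n_px, n_px)
  ext <- n_px * spec$pixel_size
  withr::with_seed(seed, {
    n <- spec$n_fibers
    cx <- runif(n, 0, ext) + origin[1]
    cy <- runif(n, 0, ext) + origin[2]
    len <- pmax(rnorm(n, spec$fiber_length_mean, spec$fiber_length_sd), 5)
    base <- if (inherits(field, "orientation_grid")) {
      grid_angle_at(field, cx, cy)
    } else {
      rep(wrap_axial(as.numeric(field)), n)
    }
    theta <- if (spec$kappa == 0) {
      runif(n, 0, 180)
    } else {
      j <- rvonmises_axial(n, mu = 0, kappa = spec$kappa)
      wrap_axial(base + ifelse(j > 90, j - 180, j))
    }
    maps <- pixel_centers(n_px, n_px, spec$pixel_size, origin)
    half_w <- spec$fiber_width / 2
    for (f in seq_len(n)) {
      th <- theta[f] * pi / 180
      ex <- len[f] / 2 * cos(th); ey <- len[f] / 2 * sin(th)
      x1 <- cx[f] - ex; x2 <- cx[f] + ex
      y1 <- cy[f] - ey; y2 <- cy[f] + ey
      pad <- (half_w + 1.5) * spec$pixel_size
      rows <- max(1, floor(maps$row(max(y1, y2) + pad))):
        min(n_px, ceiling(maps$row(min(y1, y2) - pad)))
      cols <- max(1, floor(maps$col(min(x1, x2) - pad))):
        min(n_px, ceiling(maps$col(max(x1, x2) + pad)))
      if (length(rows) == 0 || length(cols) == 0) next
      px <- maps$x(cols); py <- maps$y(rows)
      # distance from pixel centers to the segment
      X <- matrix(px, length(rows), length(cols), byrow = TRUE)
      Y <- matrix(py, length(rows), length(cols))
      vx <- x2 - x1; vy <- y2 - y1
      tt <- pmin(pmax(((X - x1) * vx + (Y - y1) * vy) / (vx^2 + vy^2), 0), 1)
      dist <- sqrt((X - (x1 + tt * vx))^2 + (Y - (y1 + tt * vy))^2) /
        spec$pixel_size
      contrib <- spec$amplitude * pmin(pmax(half_w + 0.5 - dist, 0), 1)
      img[rows, cols] <- img[rows, cols] + contrib
    }
    if (spec$psf_sigma > 0) img <- EBImage::gblur(img, spec$psf_sigma)
    img <- img + spec$background
    img <- switch(spec$noise,
      none = img,
      gaussian = img + matrix(rnorm(n_px^2, 0, spec$noise_sd), n_px, n_px),
      poisson = matrix(rpois(n_px^2, pmax(img, 0) * spec$poisson_scale),
                       n_px, n_px) / spec$poisson_scale
    )
    img <- pmax(img, 0)
    list(image = img,
         truth = tibble(fiber = seq_len(n), x = cx, y = cy,
                        theta = theta, length = len))
  })
}

#' Binary disk mask for a spheroid
#'
#' @param center Disk center `c(x, y)` in micrometres (image physical
#'   frame; see [image_spec()]).
#' @param radius Disk radius, um (> 0).
#' @param spec An [image_spec()] (canvas size and pixel size).
#' @param origin Physical coordinates of the image's lower-left corner.
#' @return A 0/1 matrix; pixels whose centers fall inside the disk are 1.
#'   Disks extending beyond the canvas are clipped.
#' @export
spheroid_mask <- function(center, radius, spec = image_spec(),
                          origin = c(0, 0)) {
  stopifnot(radius > 0, inherits(spec, "image_spec"))
  n_px <- spec$size
  maps <- pixel_centers(n_px, n_px, spec$pixel_size, origin)
  X <- matrix(maps$x(seq_len(n_px)), n_px, n_px, byrow = TRUE)
  Y <- matrix(maps$y(seq_len(n_px)), n_px, n_px)
  ((X - center[1])^2 + (Y - center[2])^2 <= radius^2) * 1
}

#' Passive tracer trajectories in the flow
#'
#' Advects point tracers with the velocity field (the synthetic analogue of
#' beads moving in the polymerizing gel), one polyline per tracer.
#'
#' @param model A [flow_model()].
#' @param n Number of tracers; released on a line upstream of the obstacle
#'   unless `start` is given.
#' @param dt Time step, s.
#' @param t_max Integration time, s.
#' @param seed RNG seed for the default release positions.
#' @param start Optional data frame `x`, `y` of release points.
#' @return A tibble `tracer`, `t`, `x`, `y`.
#' @export
tracer_trajectories <- function(model, n = 12, dt = 5, t_max = 1500,
                                seed = 1, start = NULL) {
  stopifnot(inherits(model, "flow_model"))
  a <- model$radius
  if (is.null(start)) {
    start <- withr::with_seed(seed, tibble(
      x = model$obstacle$center[1] + runif(n, -4 * a, 4 * a),
      y = model$obstacle$center[2] + 5 * a
    ))
  }
  check_in_domain(start$x, start$y, model)
  sol <- advect_rods(start$x, start$y, rep(0, nrow(start)), model, dt, t_max)
  purrr::map(seq_len(nrow(start)), function(k) {
    tibble(tracer = k, t = sol$t, x = sol$x[, k], y = sol$y[, k])
  }) |> list_rbind()
}

#' Write / read a grayscale image as TIFF
#'
#' Thin wrappers over the tiff package; intensities are clipped to
#' `[0, 1]` on write (32-bit float TIFF).
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` returns a numeric matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
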