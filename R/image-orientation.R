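#' Aligned-window definition for the degree of alignment
#'
#' Fibers within 90 +- 22 degrees of the flow axis count as aligned with the
#' main flow. The window is realized as the 46 integer-degree histogram bins
#' 68..113, so that the uniform-distribution baseline is exactly
#' 46/180 = 25.56%, matching the printed constant (the closed interval
#' 68-112 would span 45 bins, 25.0%).
#'
#' @param bins Integer bin centers (degrees) forming the aligned window.
#' @return An `alignment_params` list with `bins` and `baseline`
#'   (= `length(bins) / 180`).
#' @export
alignment_params <- function(bins = 68:113) {
  stopifnot(all(bins %in% 0:179), !anyDuplicated(bins))
  structure(list(bins = as.integer(bins), baseline = length(bins) / 180),
            class = "alignment_params")
}

#' Preprocess a fiber image for orientation analysis
#'
#' Gaussian smoothing, rolling-ball style background subtraction (grayscale
#' morphological opening with a disk structuring element), and Otsu
#' thresholding of the background-subtracted image into a foreground mask.
#' Adding a constant offset to the input leaves the background-subtracted
#' image unchanged. An empty foreground is flagged with a warning and
#' passed downstream as an empty mask.
#'
#' @param image Numeric 2D matrix.
#' @param blur_sigma Gaussian smoothing sigma, pixels.
#' @param rolling_radius Structuring-element radius, pixels; should exceed
#'   the fiber width.
#' @param threshold `"otsu"` or a numeric threshold on the
#'   background-subtracted image.
#' @return A `preprocessed_image` list: `image` (background-subtracted,
#'   smoothed), `mask` (logical matrix), `params`.
#' @export
preprocess_fiber_image <- function(image, blur_sigma = 1,
                                   rolling_radius = 25,
                                   threshold = "otsu") {
  stopifnot(is.matrix(image), is.numeric(image))
  sm <- if (blur_sigma > 0) EBImage::gblur(image, blur_sigma) else image
  brush_size <- 2 * round(rolling_radius) + 1
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  background <- EBImage::dilate(EBImage::erode(sm, brush), brush)
  sub <- pmax(sm - background, 0)
  thr <- if (identical(threshold, "otsu")) {
    rng <- max(sub)
    if (rng <= 0) Inf else EBImage::otsu(EBImage::Image(sub / rng)) * rng
  } else {
    as.numeric(threshold)
  }
  mask <- sub > thr
  if (!any(mask)) {
    warn("empty foreground after preprocessing",
         class = "fiberflow_empty_foreground")
  }
  structure(list(image = sub, mask = mask,
                 params = list(blur_sigma = blur_sigma,
                               rolling_radius = rolling_radius,
                               threshold = thr)),
            class = "preprocessed_image")
}

# Sobel gradients on a matrix (edge rows/cols replicated); returns the
# per-pixel local orientation (gradient direction + 90, axial) and squared
# gradient magnitude, in image-matrix coordinates (row 1 = top, so the
# physical y axis is -row).
pixel_orientations <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  P <- rbind(image[1, ], image, image[nr, ])
  P <- cbind(P[, 1], P, P[, nc])
  ctr_r <- 2:(nr + 1); ctr_c <- 2:(nc + 1)
  # separable Sobel: smooth [1 2 1] across one axis, difference across the other
  sm_r <- P[ctr_r - 1, ] + 2 * P[ctr_r, ] + P[ctr_r + 1, ]   # smoothed over rows
  gx <- sm_r[, ctr_c + 1] - sm_r[, ctr_c - 1]                # d/dcol
  sm_c <- P[, ctr_c - 1] + 2 * P[, ctr_c] + P[, ctr_c + 1]   # smoothed over cols
  gr <- sm_c[ctr_r + 1, ] - sm_c[ctr_r - 1, ]                # d/drow
  gy <- -gr                                                  # physical y is -row
  list(theta = wrap_axial(atan2(gy, gx) * 180 / pi + 90),
       w = gx^2 + gy^2)
}

#' Fiber-orientation histogram by the local gradient method
#'
#' Per-pixel intensity gradients (3x3 Sobel kernels) give a local fiber
#' orientation (gradient direction rotated by 90 degrees, axial) weighted by
#' the squared gradient magnitude over the foreground. Weights are binned
#' into 180 one-degree bins with centers at 0..179 degrees (180-periodic:
#' the 0/180 seam maps to bin 0) and normalized to unit mass.
#'
#' @param image A numeric matrix or a [preprocess_fiber_image()] result.
#' @param mask Optional logical matrix restricting the analysis (defaults
#'   to the preprocessed mask, or all pixels).
#' @return An `orientation_histogram`: tibble with `angle` (0..179) and
#'   `weight` (sums to 1).
#' @export
orientation_histogram <- function(image, mask = NULL) {
  if (inherits(image, "preprocessed_image")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  stopifnot(is.matrix(image))
  po <- pixel_orientations(image)
  w <- po$w
  if (!is.null(mask)) w <- w * (mask != 0)
  total <- sum(w)
  if (total <= 0) {
    abort("zero total gradient weight: orientation histogram undefined",
          class = "fiberflow_undefined_histogram")
  }
  bin <- round(po$theta) %% 180
  weight <- vapply(0:179, function(b) sum(w[bin == b]), numeric(1)) / total
  new_tibble(tibble(angle = 0:179, weight = weight),
             class = "orientation_histogram")
}

#' Degree of alignment of an orientation distribution
#'
#' The fraction of orientation mass inside the aligned window (90 +- 22
#' degrees), divided by the same fraction for a uniform fiber distribution
#' (25.56%). A uniform histogram scores exactly 1; all mass at 90 degrees
#' scores 180/46 ~ 3.91; mass entirely outside the window scores 0.
#'
#' @param hist An `orientation_histogram` (or tibble with `angle`,
#'   `weight`). Unnormalized histograms are normalized with a message.
#' @param params An [alignment_params()].
#' @return The degree of alignment (dimensionless).
#' @export
degree_of_alignment <- function(hist, params = alignment_params()) {
  stopifnot(all(c("angle", "weight") %in% names(hist)),
            inherits(params, "alignment_params"))
  w <- hist$weight
  if (any(w < 0)) abort("histogram weights must be nonnegative")
  total <- sum(w)
  if (total <= 0) abort("histogram has zero mass")
  if (abs(total - 1) > 1e-8) {
    inform(sprintf("normalizing histogram (total mass %.6g)", total))
    w <- w / total
  }
  sum(w[hist$angle %in% params$bins]) / params$baseline
}

#' Per-box orientation grid from an image
#'
#' Divides the image into square boxes of side `box_size` micrometres and
#' computes each box's axial circular mean of the local-gradient
#' orientations, weighted by squared gradient magnitude over the foreground.
#' Boxes with no foreground signal (e.g. inside a spheroid mask) are filled
#' from the nearest sampled box and flagged.
#'
#' @param image A numeric matrix or [preprocess_fiber_image()] result.
#' @param mask Optional logical matrix (foreground); pixels outside it get
#'   zero weight.
#' @param pixel_size Micrometres per pixel.
#' @param box_size Box side, um (default 103).
#' @param origin Physical coordinates of the image's lower-left corner.
#' @return An `orientation_grid`.
#' @export
orientation_grid_from_image <- function(image, mask = NULL, pixel_size = 1,
                                        box_size = 103, origin = c(0, 0)) {
  if (inherits(image, "preprocessed_image")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  stopifnot(is.matrix(image), pixel_size > 0)
  po <- pixel_orientations(image)
  w <- po$w
  if (!is.null(mask)) w <- w * (mask != 0)
  nr <- nrow(image); nc <- ncol(image)
  keep <- w > 0
  if (!any(keep)) {
    abort("no foreground signal: all boxes empty",
          class = "fiberflow_empty_grid")
  }
  rc <- which(keep, arr.ind = TRUE)
  samples <- tibble(
    x = origin[1] + (rc[, 2] - 0.5) * pixel_size,
    y = origin[2] + (nr - rc[, 1] + 0.5) * pixel_size,
    theta = po$theta[keep],
    w = w[keep]
  )
  spec <- grid_spec(xlim = c(origin[1], origin[1] + nc * pixel_size),
                    ylim = c(origin[2], origin[2] + nr * pixel_size),
                    box_size = box_size)
  orientation_grid_from_samples(samples, spec)
}

#' @method autoplot orientation_histogram
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  params <- alignment_params()
  df <- mutate(as_tibble(object),
               aligned = .data$angle %in% params$bins)
  ggplot(df, aes(x = .data$angle, y = .data$weight, fill = .data$aligned)) +
    geom_col(width = 1) +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue")) +
    labs(x = "fiber orientation (deg)", y = "fraction",
         fill = "90° ± 22° window") +
    theme_minimal()
}
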