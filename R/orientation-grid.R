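#' Square-box grid specification for orientation fields
#'
#' The invasion model reads fiber orientation from a grid of square boxes of
#' side `box_size` (default 103 um) covering the field of view. The grid is
#' anchored at `xlim[1], ylim[1]` (lower-left corner of box (1,1)) and covers
#' the requested ranges with whole boxes. The default is a 19 x 19 grid with
#' the central box centered on the origin, i.e. on the spheroid.
#'
#' @param xlim,ylim Ranges to cover, micrometres.
#' @param box_size Box side in micrometres.
#' @return A `grid_spec` list with `origin`, `box_size`, `nx`, `ny`.
#' @export
grid_spec <- function(xlim = c(-978.5, 978.5), ylim = c(-978.5, 978.5),
                      box_size = 103) {
  stopifnot(box_size > 0, diff(xlim) > 0, diff(ylim) > 0)
  nx <- max(1L, as.integer(ceiling(diff(xlim) / box_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling(diff(ylim) / box_size - 1e-9)))
  structure(list(origin = c(xlim[1], ylim[1]), box_size = box_size,
                 nx = nx, ny = ny),
            class = "grid_spec")
}

#' Grid specification anchored to a spheroid
#'
#' Chooses between the two symmetric grid anchorings (a box centered on the
#' spheroid center, or box corners meeting at it) so that the box row/column
#' containing the spheroid surface is centered as close to the surface as
#' possible. With 103-um boxes the orientation bands hugging the surface
#' (tangential ring, perpendicular upstream cap) are thinner than a box, so
#' a box straddling the surface averages mostly over the band, while a box
#' whose edge sits at the surface dilutes the band with far-field fibers.
#'
#' @param radius Spheroid radius, um.
#' @param half_extent Half-width of the field of view, um.
#' @param box_size Box side, um.
#' @return A [grid_spec()].
#' @export
grid_spec_for_spheroid <- function(radius, half_extent = 927,
                                   box_size = 103) {
  stopifnot(radius > 0, half_extent > radius)
  # candidate surface-box centers: box_size*k (center-anchored) or
  # box_size*(k + 1/2) (corner-anchored)
  dev_center <- min(abs(radius - box_size * (0:50)))
  dev_corner <- min(abs(radius - box_size * (0:50 + 0.5)))
  n_half <- ceiling(half_extent / box_size)
  if (dev_center <= dev_corner) {
    half <- box_size * (n_half + 0.5)
    grid_spec(c(-half, half), c(-half, half), box_size)
  } else {
    half <- box_size * n_half
    grid_spec(c(-half, half), c(-half, half), box_size)
  }
}

new_orientation_grid <- function(df, spec) {
  out <- new_tibble(df, class = "orientation_grid")
  attr(out, "origin") <- spec$origin
  attr(out, "box_size") <- spec$box_size
  attr(out, "nx") <- spec$nx
  attr(out, "ny") <- spec$ny
  out
}

#' Build an orientation grid from angle samples
#'
#' Deposits point samples of axial fiber angles into grid boxes and computes
#' the per-box axial circular mean (angle doubling), sample count, and
#' coherence. Boxes without samples are filled from the nearest sampled box
#' (by box-center distance) and flagged `filled = TRUE`: the invasion
#' simulator needs a total field, including inside the spheroid.
#'
#' @param samples Data frame with columns `x`, `y` (um) and `theta`
#'   (axial degrees); optional `w` weights.
#' @param spec A [grid_spec()].
#' @return An `orientation_grid`: a tibble with one row per box, columns
#'   `i`, `j` (box indices), `x`, `y` (box centers, um), `alpha` (axial
#'   mean angle, degrees in `[0, 180)`), `count`, `coherence`, `filled`.
#' @export
orientation_grid_from_samples <- function(samples, spec) {
  stopifnot(inherits(spec, "grid_spec"),
            all(c("x", "y", "theta") %in% names(samples)))
  if (nrow(samples) == 0L) {
    abort("no angle samples supplied", class = "fiberflow_empty_grid")
  }
  if (!"w" %in% names(samples)) samples$w <- 1
  d <- spec$box_size
  idx <- tibble(
    i = pmin(pmax(floor((samples$x - spec$origin[1]) / d) + 1L, 1L), spec$nx),
    j = pmin(pmax(floor((samples$y - spec$origin[2]) / d) + 1L, 1L), spec$ny),
    theta = wrap_axial(samples$theta),
    w = samples$w
  )
  stats <- idx |>
    group_by(.data$i, .data$j) |>
    summarise(alpha = axial_mean(.data$theta, .data$w),
              count = dplyr::n(),
              coherence = axial_coherence(.data$theta, .data$w),
              .groups = "drop")
  boxes <- expand_grid(i = seq_len(spec$nx), j = seq_len(spec$ny)) |>
    mutate(x = spec$origin[1] + (.data$i - 0.5) * d,
           y = spec$origin[2] + (.data$j - 0.5) * d) |>
    left_join(stats, by = c("i", "j")) |>
    mutate(filled = is.na(.data$alpha),
           count = ifelse(is.na(.data$count), 0L, .data$count))
  boxes <- fill_empty_boxes(boxes)
  new_orientation_grid(boxes, spec)
}

# nearest-neighbour propagation into empty boxes (grids are small)
fill_empty_boxes <- function(boxes) {
  empty <- which(boxes$filled)
  good <- which(!boxes$filled)
  if (length(empty) == 0L) return(boxes)
  if (length(good) == 0L) {
    abort("orientation grid has no sampled boxes",
          class = "fiberflow_empty_grid")
  }
  for (k in empty) {
    d2 <- (boxes$x[good] - boxes$x[k])^2 + (boxes$y[good] - boxes$y[k])^2
    src <- good[which.min(d2)]
    boxes$alpha[k] <- boxes$alpha[src]
    boxes$coherence[k] <- boxes$coherence[src]
  }
  boxes
}

#' Canonical orientation fields for testing and sweeps
#'
#' Controlled fields on a grid: `"uniform"` (every box at `angle`),
#' `"radial"` (fiber axis pointing away from `center`), `"tangential"`
#' (perpendicular to radial), and `"isotropic"` (independent uniform axial
#' angles, reproducible from `seed`).
#'
#' @param kind One of `"uniform"`, `"radial"`, `"tangential"`, `"isotropic"`.
#' @param spec A [grid_spec()].
#' @param center Reference point for radial/tangential fields.
#' @param angle Uniform-field angle, degrees.
#' @param seed RNG seed for `"isotropic"`.
#' @return An `orientation_grid`.
#' @export
canonical_field <- function(kind = c("uniform", "radial", "tangential",
                                     "isotropic"),
                            spec = grid_spec(), center = c(0, 0),
                            angle = 90, seed = 1) {
  kind <- rlang::arg_match(kind)
  d <- spec$box_size
  boxes <- expand_grid(i = seq_len(spec$nx), j = seq_len(spec$ny)) |>
    mutate(x = spec$origin[1] + (.data$i - 0.5) * d,
           y = spec$origin[2] + (.data$j - 0.5) * d)
  polar <- atan2(boxes$y - center[2], boxes$x - center[1]) * 180 / pi
  boxes$alpha <- switch(kind,
    uniform = rep(wrap_axial(angle), nrow(boxes)),
    radial = wrap_axial(polar),
    tangential = wrap_axial(polar + 90),
    isotropic = withr::with_seed(seed, runif(nrow(boxes), 0, 180))
  )
  boxes$count <- 1L
  boxes$coherence <- if (kind == "isotropic") 0 else 1
  boxes$filled <- FALSE
  new_orientation_grid(boxes, spec)
}

# nx x ny matrix of box angles, for fast lookup in the simulator
grid_alpha_matrix <- function(grid) {
  m <- matrix(NA_real_, attr(grid, "nx"), attr(grid, "ny"))
  m[cbind(grid$i, grid$j)] <- grid$alpha
  m
}

#' Look up the local fiber angle at arbitrary points
#'
#' Maps each point to its grid box; points outside the gridded field of view
#' are assigned the nearest box (index clamping), so the field is total.
#'
#' @param grid An `orientation_grid`.
#' @param x,y Coordinates in micrometres (vectorized).
#' @return Axial angles in degrees.
#' @export
grid_angle_at <- function(grid, x, y) {
  d <- attr(grid, "box_size"); o <- attr(grid, "origin")
  i <- pmin(pmax(floor((x - o[1]) / d) + 1L, 1L), attr(grid, "nx"))
  j <- pmin(pmax(floor((y - o[2]) / d) + 1L, 1L), attr(grid, "ny"))
  grid_alpha_matrix(grid)[cbind(i, j)]
}

#' Read/write orientation grids as plain CSV
#'
#' The grid table is stored as CSV with `#`-prefixed header lines carrying
#' the grid metadata (origin, box size, dimensions).
#'
#' @param grid An `orientation_grid`.
#' @param path File path.
#' @return `write_orientation_grid()` returns `path` invisibly;
#'   `read_orientation_grid()` returns the grid.
#' @export
write_orientation_grid <- function(grid, path) {
  meta <- sprintf("# origin %.10g %.10g\n# box_size %.10g\n# dim %d %d",
                  attr(grid, "origin")[1], attr(grid, "origin")[2],
                  attr(grid, "box_size"), attr(grid, "nx"), attr(grid, "ny"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(grid), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_grid
#' @export
read_orientation_grid <- function(path) {
  lines <- readLines(path, n = 3)
  origin <- as.numeric(strsplit(lines[1], " ")[[1]][3:4])
  box_size <- as.numeric(strsplit(lines[2], " ")[[1]][3])
  dims <- as.integer(strsplit(lines[3], " ")[[1]][3:4])
  df <- utils::read.csv(path, comment.char = "#")
  spec <- structure(list(origin = origin, box_size = box_size,
                         nx = dims[1], ny = dims[2]), class = "grid_spec")
  new_orientation_grid(as_tibble(df), spec)
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("<orientation_grid> %d x %d boxes of %.0f um, %d filled by propagation\n",
              attr(x, "nx"), attr(x, "ny"), attr(x, "box_size"),
              sum(x$filled)))
  NextMethod()
}

#' Plot an orientation grid as oriented line segments
#'
#' @param object An `orientation_grid`.
#' @param ... Unused.
#' @return A ggplot object: one segment per box along the local fiber axis,
#'   colored by coherence.
#' @method autoplot orientation_grid
#' @export
autoplot.orientation_grid <- function(object, ...) {
  d <- attr(object, "box_size")
  df <- as_tibble(object) |>
    mutate(dx = 0.4 * d * cos(.data$alpha * pi / 180),
           dy = 0.4 * d * sin(.data$alpha * pi / 180))
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_segment(aes(xend = .data$x + .data$dx, yend = .data$y + .data$dy,
                     x = .data$x - .data$dx, y = .data$y - .data$dy,
                     colour = .data$coherence)) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "coherence") +
    theme_minimal()
}
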