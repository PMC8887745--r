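#' Configuration of the anisotropic random-walk invasion model
#'
#' Cells perform a 2D random walk whose step size depends on the local fiber
#' orientation: at each time step a cell takes one of four equiprobable
#' moves — forward/backward parallel to the local fiber axis (step `k_p`) or
#' forward/backward perpendicular to it (step `k_v`). Step sizes are
#' calibrated from the distance the invasion fronts travel in one day:
#' `r_p` parallel (downstream front, default 220 um/day) and `r_v`
#' perpendicular (default 0: complete blockage of migration across fibers,
#' the parameter set that best matches the observed spheroid shapes).
#'
#' @param r_p,r_v Day-scale displacement parallel/perpendicular to fibers,
#'   um/day.
#' @param n_steps Time steps per day (the model's `N`).
#' @param days Number of simulated days.
#' @param n_cells Number of cells.
#' @param center Spheroid center, um.
#' @param radius Initial spheroid radius, um (spheroids are 250-350 um in
#'   diameter; default 150 um radius).
#' @param seed RNG seed; simulations are bit-reproducible given the seed.
#' @param seeding `"disk"` (cells uniform over the spheroid disk, the
#'   default: the spheroid is filled with cells) or `"boundary"` (uniform on
#'   the circle).
#' @param step_scaling `"sqrt"`: per-step size `k = r / sqrt(N)` (diffusive
#'   reading; front growth goes as sqrt(time)); `"linear"`: `k = r / N`.
#' @param redraw_null_moves If `TRUE`, perpendicular moves with `k_v = 0`
#'   are re-drawn instead of consuming the time step as a null move.
#'   Default `FALSE`: all four moves are equiprobable as stated, so with
#'   `k_v = 0` half the steps displace nothing.
#' @return A `sim_config` list.
#' @export
sim_config <- function(r_p = 220, r_v = 0, n_steps = 100, days = 3,
                       n_cells = 1000, center = c(0, 0), radius = 150,
                       seed = 1, seeding = c("disk", "boundary"),
                       step_scaling = c("sqrt", "linear"),
                       redraw_null_moves = FALSE) {
  seeding <- rlang::arg_match(seeding)
  step_scaling <- rlang::arg_match(step_scaling)
  if (r_p < 0 || r_v < 0) abort("step sizes must be nonnegative")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (radius <= 0) abort("spheroid radius must be positive")
  structure(list(r_p = r_p, r_v = r_v, n_steps = as.integer(n_steps),
                 days = as.integer(days), n_cells = as.integer(n_cells),
                 center = as.numeric(center), radius = radius,
                 seed = as.integer(seed), seeding = seeding,
                 step_scaling = step_scaling,
                 redraw_null_moves = isTRUE(redraw_null_moves)),
            class = "sim_config")
}

#' Per-step sizes from day-scale displacements
#'
#' Under the default diffusive scaling `k = r / sqrt(N)`: after `N` steps a
#' 1D `+-k` walk has RMS displacement `k * sqrt(N) = r`, so the day-scale
#' calibration distance is recovered in root-mean-square and fronts grow
#' with the square root of time. The `"linear"` alternative `k = r / N`
#' (ballistic sum) is retained for sensitivity analysis.
#'
#' @param r_p,r_v Day-scale displacements, um/day.
#' @param n_steps Steps per day.
#' @param step_scaling `"sqrt"` or `"linear"`.
#' @return A list with `k_p`, `k_v` in um/step.
#' @examples
#' step_sizes(220, 0, 100) # k_p = 22
#' @export
step_sizes <- function(r_p, r_v, n_steps, step_scaling = c("sqrt", "linear")) {
  step_scaling <- rlang::arg_match(step_scaling)
  if (n_steps < 1) abort("n_steps must be >= 1")
  den <- if (step_scaling == "sqrt") sqrt(n_steps) else n_steps
  list(k_p = r_p / den, k_v = r_v / den)
}

#' Seed the initial cell configuration
#'
#' Cells are distributed on the spheroid: uniformly over the disk (default;
#' the spheroid is filled with cells) or uniformly on its boundary circle.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `cell`, `x`, `y`.
#' @export
seed_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  withr::with_seed(config$seed, {
    ang <- runif(n, 0, 2 * pi)
    r <- if (config$seeding == "disk") {
      config$radius * sqrt(runif(n))
    } else {
      rep(config$radius, n)
    }
    tibble(cell = seq_len(n),
           x = config$center[1] + r * cos(ang),
           y = config$center[2] + r * sin(ang))
  })
}

#' One step of the four-move anisotropic walk
#'
#' For each cell, one of the four moves is chosen uniformly:
#' parallel `(dx, dy) = +-k_p (cos a, sin a)` or perpendicular
#' `+-k_v (cos(a + 90), sin(a + 90))`, where `a` is the local fiber angle.
#' Cells may overlap and the plane is unbounded. Uses the current RNG
#' stream; callers seed it (as [simulate_invasion()] does).
#'
#' @param frame Data frame with columns `x`, `y` (one row per cell).
#' @param alpha Local fiber angle per cell, degrees.
#' @param k List with `k_p`, `k_v` (um/step), from [step_sizes()].
#' @param redraw_null_moves See [sim_config()].
#' @return The frame with updated `x`, `y`.
#' @export
walk_step <- function(frame, alpha, k, redraw_null_moves = FALSE) {
  n <- nrow(frame)
  if (redraw_null_moves && k$k_v == 0) {
    move <- sample.int(2L, n, replace = TRUE)
  } else {
    move <- sample.int(4L, n, replace = TRUE)
  }
  a <- alpha * pi / 180
  ca <- cos(a); sa <- sin(a)
  par_sign <- ifelse(move == 1L, 1, ifelse(move == 2L, -1, 0))
  perp_sign <- ifelse(move == 3L, 1, ifelse(move == 4L, -1, 0))
  # cos(a + 90) = -sin(a), sin(a + 90) = cos(a)
  frame$x <- frame$x + par_sign * k$k_p * ca - perp_sign * k$k_v * sa
  frame$y <- frame$y + par_sign * k$k_p * sa + perp_sign * k$k_v * ca
  frame
}

#' Simulate spheroid invasion on an orientation field
#'
#' Runs the four-move anisotropic random walk for `days * n_steps` steps on
#' the given orientation grid (extended beyond the gridded field of view by
#' nearest-box lookup), recording cell positions at each day boundary.
#' No proliferation, no cell-cell interaction, overlap allowed; the spheroid
#' interior is not an obstacle.
#'
#' @param grid An `orientation_grid` (see [synthesize_orientation_field()],
#'   [canonical_field()], [orientation_grid_from_image()]).
#' @param config A [sim_config()].
#' @return An `invasion_sim` object: list with `positions` (tibble `cell`,
#'   `day`, `x`, `y`; day 0 is the seeded configuration), `config`, and the
#'   grid metadata.
#' @export
simulate_invasion <- function(grid, config = sim_config()) {
  stopifnot(inherits(grid, "orientation_grid"), inherits(config, "sim_config"))
  k <- step_sizes(config$r_p, config$r_v, config$n_steps,
                  config$step_scaling)
  alpha_mat <- grid_alpha_matrix(grid)
  d <- attr(grid, "box_size"); o <- attr(grid, "origin")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  lookup <- function(x, y) {
    i <- pmin(pmax(floor((x - o[1]) / d) + 1L, 1L), nx)
    j <- pmin(pmax(floor((y - o[2]) / d) + 1L, 1L), ny)
    alpha_mat[cbind(i, j)]
  }
  frame <- seed_cells(config)
  frames <- vector("list", config$days + 1L)
  frames[[1]] <- mutate(frame, day = 0L)
  withr::with_seed(config$seed + 1L, {
    for (day in seq_len(config$days)) {
      for (s in seq_len(config$n_steps)) {
        alpha <- lookup(frame$x, frame$y)
        frame <- walk_step(frame, alpha, k, config$redraw_null_moves)
      }
      frames[[day + 1L]] <- mutate(frame, day = day)
    }
  })
  positions <- bind_rows(frames) |>
    select("cell", "day", "x", "y")
  structure(list(positions = positions, config = config,
                 grid_meta = list(origin = o, box_size = d,
                                  nx = nx, ny = ny)),
            class = "invasion_sim")
}

#' @export
print.invasion_sim <- function(x, ...) {
  cat(sprintf(
    "<invasion_sim> %d cells, %d day(s) x %d steps, r_p = %g, r_v = %g um/day (seed %d)\n",
    x$config$n_cells, x$config$days, x$config$n_steps,
    x$config$r_p, x$config$r_v, x$config$seed))
  invisible(x)
}

#' @describeIn simulate_invasion Tidy the per-cell positions (one row per
#'   cell per recorded day).
#' @param x,object An `invasion_sim`.
#' @param ... Unused.
#' @method tidy invasion_sim
#' @export
tidy.invasion_sim <- function(x, ...) {
  x$positions
}

#' @describeIn simulate_invasion One-row model summary with the
#'   configuration and the mean radial distance from the spheroid center at
#'   the final day.
#' @method glance invasion_sim
#' @export
glance.invasion_sim <- function(x, ...) {
  fin <- filter(x$positions, .data$day == max(.data$day))
  tibble(n_cells = x$config$n_cells, days = x$config$days,
         n_steps = x$config$n_steps, r_p = x$config$r_p, r_v = x$config$r_v,
         seed = x$config$seed, seeding = x$config$seeding,
         mean_final_radius = mean(sqrt((fin$x - x$config$center[1])^2 +
                                         (fin$y - x$config$center[2])^2)))
}

#' @describeIn simulate_invasion Plot cell positions per recorded day with
#'   the initial spheroid outline.
#' @method autoplot invasion_sim
#' @export
autoplot.invasion_sim <- function(object, ...) {
  circ <- tibble(t = seq(0, 2 * pi, length.out = 181)) |>
    mutate(x = object$config$center[1] + object$config$radius * cos(.data$t),
           y = object$config$center[2] + object$config$radius * sin(.data$t))
  ggplot(object$positions, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 0.3, alpha = 0.5) +
    geom_path(data = circ, colour = "red") +
    facet_wrap(~day, labeller = label_both) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}
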