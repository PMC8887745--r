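#' Sector-wise invasion-front distance
#'
#' The invasion front in a direction is the mean distance beyond the initial
#' spheroid boundary of the `m` cells that travelled furthest into that
#' direction. Directions are 8 polar sectors of 45 degrees centered at 0,
#' 45, ..., 315 degrees about the spheroid center; with the flow running
#' from top to bottom, 90 is the upstream and 270 the downstream sector.
#' Distances are measured radially; the m-th outmost cell is tie-broken by
#' cell index for determinism. If a sector holds fewer than `m` cells, all
#' of its cells are used and the row is flagged.
#'
#' @param frame Data frame of cell positions (`x`, `y`), one row per cell.
#' @param center Spheroid center `c(x, y)`, um.
#' @param radius0 Initial spheroid radius, um.
#' @param sectors Number of equal sectors (default 8).
#' @param m Number of outmost cells per sector (default 10).
#' @return A tibble with one row per sector: `sector` (center angle,
#'   degrees), `n_cells`, `front` (um, floored at 0), `flagged`.
#' @export
sector_front_distance <- function(frame, center, radius0, sectors = 8,
                                  m = 10) {
  stopifnot(nrow(frame) > 0, radius0 >= 0, sectors >= 1, m >= 1)
  width <- 360 / sectors
  dx <- frame$x - center[1]; dy <- frame$y - center[2]
  polar <- (atan2(dy, dx) * 180 / pi) %% 360
  sec <- (floor((polar + width / 2) / width) %% sectors) * width
  excess <- sqrt(dx^2 + dy^2) - radius0
  df <- tibble(sector = sec, excess = excess,
               cell = seq_along(excess))
  centers <- seq(0, 360 - width, by = width)
  purrr::map(centers, function(ctr) {
    rows <- df |> filter(.data$sector == ctr) |>
      arrange(desc(.data$excess), .data$cell)
    n_in <- nrow(rows)
    top <- head(rows$excess, m)
    tibble(sector = ctr, n_cells = n_in,
           front = if (n_in == 0) 0 else mean(pmax(top, 0)),
           flagged = n_in < m)
  }) |> list_rbind()
}

#' Invasion distance relative to the initial spheroid radius
#'
#' Normalizes front distances by the initial spheroid radius, giving a
#' dimensionless measure of how far the front has travelled relative to the
#' spheroid size.
#'
#' @param table A sector-front table (any tibble with a `front` column).
#' @param radius0 Initial spheroid radius, um (> 0).
#' @return The table with `front` replaced by `front / radius0` (column
#'   `relative_front`).
#' @export
relative_invasion <- function(table, radius0) {
  if (!is.numeric(radius0) || radius0 <= 0) {
    abort("radius0 must be positive", class = "fiberflow_invalid_value")
  }
  mutate(as_tibble(table), relative_front = .data$front / radius0)
}

#' Daily sector-front table of a simulation
#'
#' Applies [sector_front_distance()] to each recorded day of an invasion
#' simulation.
#'
#' @param sim An `invasion_sim`.
#' @param sectors,m As in [sector_front_distance()].
#' @return A tibble `day`, `sector`, `n_cells`, `front`, `flagged`.
#' @export
invasion_front_table <- function(sim, sectors = 8, m = 10) {
  stopifnot(inherits(sim, "invasion_sim"))
  sim$positions |>
    group_by(.data$day) |>
    dplyr::group_modify(~ sector_front_distance(.x, sim$config$center,
                                                sim$config$radius,
                                                sectors, m)) |>
    ungroup()
}

#' Sweep the perpendicular step size
#'
#' Repeats the invasion simulation for each perpendicular day-scale step
#' size `r_v`, averaging sector fronts over replicate seeds, and reports the
#' downstream/upstream asymmetry index. Reducing `r_v` increases the shape
#' asymmetry; the sweep operationalizes the model selection that found
#' `r_v = 0` (no migration across fibers) to match the experiments best.
#'
#' @param config Base [sim_config()]; its `r_v` is overridden.
#' @param grid An `orientation_grid`.
#' @param r_v Perpendicular day-scale step sizes to sweep, um/day.
#' @param replicates Replicate seeds per `r_v` (default 10, as in the
#'   averaged simulation figures).
#' @param seed Base seed from which replicate seeds are derived.
#' @param sectors,m As in [sector_front_distance()].
#' @return An `rv_sweep` object: list with `fronts` (tibble `r_v`, `day`,
#'   `sector`, `front` averaged over replicates) and `asymmetry` (tibble
#'   `r_v`, `index`: mean over days >= 1 of downstream/upstream front).
#' @export
sweep_perpendicular_step <- function(config, grid,
                                     r_v = c(0, 60, 120, 220),
                                     replicates = 10, seed = 1,
                                     sectors = 8, m = 10) {
  stopifnot(inherits(config, "sim_config"))
  fronts <- purrr::imap(r_v, function(rv, k) {
    purrr::map(seq_len(replicates), function(rep) {
      cfg <- config
      cfg$r_v <- rv
      cfg$seed <- as.integer(seed + 7919L * rep + 104729L * k)
      sim <- simulate_invasion(grid, cfg)
      invasion_front_table(sim, sectors, m) |>
        mutate(r_v = rv, replicate = rep)
    }) |> list_rbind()
  }) |> list_rbind() |>
    group_by(.data$r_v, .data$day, .data$sector) |>
    summarise(front = mean(.data$front), .groups = "drop")
  down <- 270; up <- 90
  asym <- fronts |>
    filter(.data$day >= 1, .data$sector %in% c(down, up)) |>
    tidyr::pivot_wider(names_from = "sector", values_from = "front") |>
    mutate(ratio = .data[[as.character(down)]] / .data[[as.character(up)]]) |>
    group_by(.data$r_v) |>
    summarise(index = mean(.data$ratio), .groups = "drop")
  structure(list(fronts = fronts, asymmetry = asym), class = "rv_sweep")
}

#' @describeIn sweep_perpendicular_step Tidy the replicate-averaged fronts.
#' @param x,object An `rv_sweep`.
#' @param ... Unused.
#' @method tidy rv_sweep
#' @export
tidy.rv_sweep <- function(x, ...) x$fronts

#' @describeIn sweep_perpendicular_step The per-`r_v` asymmetry indices.
#' @method glance rv_sweep
#' @export
glance.rv_sweep <- function(x, ...) x$asymmetry

#' @describeIn sweep_perpendicular_step Fronts by sector, faceted by `r_v`.
#' @method autoplot rv_sweep
#' @export
autoplot.rv_sweep <- function(object, ...) {
  ggplot(object$fronts,
         aes(x = .data$sector, y = .data$front,
             colour = factor(.data$day), group = .data$day)) +
    geom_line() + geom_point() +
    facet_wrap(~r_v, labeller = label_both) +
    labs(x = "sector center (deg)", y = "front distance (µm)",
         colour = "day") +
    theme_minimal()
}

#' Root-mean-square mismatch between two sector-front tables
#'
#' A scalar measure of how well one invasion shape matches another: per day,
#' the RMS over sectors of the front-distance difference, averaged over the
#' days both tables share. Symmetric in its arguments.
#'
#' @param sim_table,reference_table Tibbles with columns `day`, `sector`,
#'   `front` over identical day/sector sets.
#' @return RMS mismatch in um.
#' @export
shape_mismatch <- function(sim_table, reference_table) {
  a <- arrange(as_tibble(sim_table), .data$day, .data$sector)
  b <- arrange(as_tibble(reference_table), .data$day, .data$sector)
  if (nrow(a) != nrow(b) ||
      !all(a$day == b$day) || !all(a$sector == b$sector)) {
    abort("tables must cover identical days and sectors",
          class = "fiberflow_invalid_value")
  }
  a |>
    mutate(sq = (.data$front - b$front)^2) |>
    group_by(.data$day) |>
    summarise(rms = sqrt(mean(.data$sq)), .groups = "drop") |>
    dplyr::pull(.data$rms) |>
    mean()
}

#' Time-scaling exponent of front growth
#'
#' Least-squares slope of `log(front)` versus `log(day)`. The diffusive walk
#' predicts an exponent of 1/2 (front distance grows with the square root of
#' time); ballistic growth gives 1. Nonpositive distances are dropped with a
#' warning.
#'
#' @param days Numeric vector of times (> 0).
#' @param fronts Front distances at those times.
#' @return The fitted exponent.
#' @examples
#' time_scaling_exponent(1:3, 100 * sqrt(1:3)) # 0.5
#' @export
time_scaling_exponent <- function(days, fronts) {
  stopifnot(length(days) == length(fronts))
  keep <- days > 0 & fronts > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d nonpositive point(s) from log-log fit",
                 sum(!keep)))
  }
  if (sum(keep) < 2) abort("need >= 2 positive time points",
                           class = "fiberflow_invalid_value")
  unname(coef(lm(log(fronts[keep]) ~ log(days[keep])))[2])
}
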