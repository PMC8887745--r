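#' Slender-rod rotation rate in a velocity gradient
#'
#' A rigid collagen fiber (length ~47.5 um, width ~5 um, aspect ratio ~10)
#' is treated in the slender-rod (infinite aspect ratio) limit of Jeffery's
#' equations: with unit orientation vector `p(theta)`,
#' `dp/dt = L p - (p' L p) p`, so the scalar rotation rate is
#' `dtheta/dt = p_perp' L p`. The antisymmetric part of `L` rotates the rod
#' rigidly; the symmetric part aligns it with the local extensional axis.
#'
#' @param theta Rod axial angle, degrees.
#' @param L 2x2 velocity-gradient tensor (1/s), `L[i,j] = dv_i/dx_j`.
#' @return Rotation rate in degrees per second.
#' @examples
#' # solid-body rotation at omega = 0.1/s turns every rod at omega
#' rod_rotation_rate(37, matrix(c(0, 0.1, -0.1, 0), 2, 2))
#' @export
rod_rotation_rate <- function(theta, L) {
  stopifnot(is.matrix(L), all(dim(L) == 2), all(is.finite(L)))
  th <- theta * pi / 180
  p <- c(cos(th), sin(th))
  pp <- c(-sin(th), cos(th))
  sum(pp * (L %*% p)) * 180 / pi
}

# vectorized rod kinematics: positions advect with the velocity, angles with
# the slender-rod rate; evaluation clamped to the obstacle boundary so rods
# slide along the disk instead of entering it.
rods_deriv <- function(t, state, parms) {
  n <- parms$n
  x <- state[seq_len(n)]
  y <- state[n + seq_len(n)]
  th <- state[2 * n + seq_len(n)] * pi / 180
  z <- complex(real = x, imaginary = y)
  v <- velocity_complex(z, parms$model, clamp = TRUE)
  g <- gradient_components(z, parms$model, clamp = TRUE)
  ct <- cos(th); st <- sin(th)
  # dtheta = p_perp' L p with L = [[ux, uy], [vx, vy]]
  dth <- (-st) * (g$ux * ct + g$uy * st) + ct * (g$vx * ct + g$vy * st)
  list(c(Re(v), Im(v), dth * 180 / pi))
}

advect_rods <- function(x0, y0, theta0, model, dt, t_max) {
  n <- length(x0)
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::ode(y = c(x0, y0, theta0), times = times, func = rods_deriv,
                      parms = list(n = n, model = model), method = "rk4")
  list(t = sol[, 1],
       x = sol[, 1 + seq_len(n), drop = FALSE],
       y = sol[, 1 + n + seq_len(n), drop = FALSE],
       theta = sol[, 1 + 2 * n + seq_len(n), drop = FALSE])
}

#' Advect a rigid rod through the flow field
#'
#' Integrates the rod center along the velocity field and the rod angle with
#' [rod_rotation_rate()] (classical RK4, fixed step, via [deSolve::ode()]).
#' Near the obstacle the evaluation point is projected radially onto the
#' boundary, so the rod deflects around the disk rather than penetrating it.
#'
#' @param state0 List or vector with `x`, `y` (um) and `theta` (degrees).
#' @param model A [flow_model()].
#' @param dt Time step, seconds.
#' @param t_max Total integration time, seconds.
#' @return A tibble with columns `t`, `x`, `y`, `theta` (axial, `[0, 180)`).
#' @export
advect_rod <- function(state0, model, dt = 4, t_max = 2000) {
  stopifnot(inherits(model, "flow_model"))
  s <- as.numeric(unlist(state0[c("x", "y", "theta")]))
  check_in_domain(s[1], s[2], model)
  sol <- advect_rods(s[1], s[2], s[3], model, dt, t_max)
  tibble(t = sol$t, x = sol$x[, 1], y = sol$y[, 1],
         theta = wrap_axial(sol$theta[, 1]))
}

#' Synthesize the flow-derived fiber-orientation field
#'
#' Emulates collagen polymerization under flow: rods are released upstream of
#' the obstacle across the channel, advected through the flow field, and
#' their axial angles recorded at every integration step ("polymerization
#' freeze" at uniform time sampling along each trajectory). All recorded
#' angles falling inside the grid and outside the obstacle are deposited
#' into grid boxes and averaged axially. The resulting field reproduces the
#' observed pattern: flow-aligned far from the spheroid, tangential
#' alongside it, perpendicular-to-flow at the upstream face, and radial
#' (flow-aligned) at the downstream face. Boxes without samples (spheroid
#' interior) are filled from the nearest sampled box.
#'
#' @param model A [flow_model()].
#' @param spec A [grid_spec()] for the deposited field.
#' @param lanes Release x-offsets (um) relative to the obstacle center;
#'   default: lanes every quarter box across the grid plus a set of
#'   near-axis lanes so the stagnation region and the wake behind the
#'   obstacle are resolved.
#' @param rods_per_lane Rods released per lane (independent jitter draws);
#'   more rods average the release jitter out of the far-field box means.
#' @param rod_angle Release angle, degrees; rods enter aligned with the flow
#'   (90 deg).
#' @param angle_jitter_sd Axial jitter (degrees, normal) on release angles.
#'   Far-field fiber orientations are spread around the flow axis, not
#'   perfectly aligned; the jitter reproduces that spread, and incidentally
#'   breaks the unstable symmetry of a rod riding the stagnation streamline
#'   (a rod at exactly 90 degrees on the axis would never turn).
#' @param dt,t_max Integration step and horizon, seconds.
#' @param seed RNG seed (release jitter only); the result is deterministic
#'   given the seed.
#' @return An `orientation_grid`.
#' @export
synthesize_orientation_field <- function(model, spec = grid_spec(),
                                         lanes = NULL, rods_per_lane = 10,
                                         rod_angle = 90,
                                         angle_jitter_sd = 8,
                                         dt = 3, t_max = 6000, seed = 1) {
  stopifnot(inherits(model, "flow_model"), inherits(spec, "grid_spec"))
  cx <- model$obstacle$center[1]
  a <- model$radius
  xmin <- spec$origin[1]; xmax <- xmin + spec$nx * spec$box_size
  ymax <- spec$origin[2] + spec$ny * spec$box_size
  if (is.null(lanes)) {
    near_axis <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30, 45, 70)
    lanes <- sort(unique(c(
      seq(xmin - cx + spec$box_size / 4, xmax - cx - spec$box_size / 4,
          by = spec$box_size / 4),
      -near_axis, near_axis
    )))
    # the exact stagnation streamline is degenerate (a rod there never
    # escapes) and its samples sit on a box boundary; the near-axis lanes
    # cover that neighbourhood symmetrically
    lanes <- lanes[lanes != 0]
  }
  if (length(lanes) < 1) abort("need at least one release lane")
  lanes <- rep(lanes, each = max(1L, as.integer(rods_per_lane)))
  y0 <- min(ymax + 3 * a, model$geometry$length / 2 - a)
  theta0 <- withr::with_seed(seed,
    wrap_axial(rod_angle + rnorm(length(lanes), sd = angle_jitter_sd)))
  sol <- advect_rods(cx + lanes, rep(y0, length(lanes)), theta0,
                     model, dt, t_max)
  samples <- tibble(x = as.vector(sol$x), y = as.vector(sol$y),
                    theta = as.vector(sol$theta)) |>
    filter(.data$x >= xmin, .data$x <= xmax,
           .data$y >= spec$origin[2], .data$y <= ymax,
           !in_obstacle(.data$x, .data$y, model, tol = 0))
  if (nrow(samples) == 0L) {
    abort("no rod samples fell inside the grid", class = "fiberflow_empty_grid")
  }
  orientation_grid_from_samples(samples, spec)
}
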