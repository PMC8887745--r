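#' Microfluidic channel geometry
#'
#' Geometry of the flat microfluidic channel in which collagen polymerizes
#' under flow. The channel is shallow (height << width), so the
#' depth-averaged flow is a Hele-Shaw (potential) flow. Defaults follow the
#' chamber used for alignment experiments: 3.8 mm wide, 17 mm long, 0.4 mm
#' high, driven at 0.2 ul/min.
#'
#' Coordinates are lab-frame micrometres, x across the channel, y along it,
#' flow running along -y (top to bottom). The channel occupies
#' `|x| <= width/2`, `|y| <= length/2`.
#'
#' @param width,length,height Channel dimensions in micrometres.
#' @param flow_rate Volumetric inflow in microlitres per minute.
#' @return A `channel_geometry` list.
#' @export
channel_geometry <- function(width = 3800, length = 17000, height = 400,
                             flow_rate = 0.2) {
  if (any(c(width, length, height) <= 0) || flow_rate < 0) {
    abort("channel dimensions must be positive and flow_rate nonnegative",
          class = "fiberflow_invalid_geometry")
  }
  if (height > width) {
    abort("shallow-channel model requires height <= width",
          class = "fiberflow_invalid_geometry")
  }
  structure(list(width = width, length = length, height = height,
                 flow_rate = flow_rate),
            class = "channel_geometry")
}

#' Mean inflow speed of the channel
#'
#' Converts the volumetric flow rate to the depth- and width-averaged speed
#' `U = Q / (width * height)`, the far-field speed of the flow model.
#'
#' @param geometry A [channel_geometry()].
#' @return Speed in micrometres per second.
#' @examples
#' mean_inflow_speed(channel_geometry()) # ~2.19 um/s at 0.2 ul/min
#' @export
mean_inflow_speed <- function(geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  q_um3_s <- geometry$flow_rate * 1e9 / 60   # ul/min -> um^3/s
  q_um3_s / (geometry$width * geometry$height)
}

#' Immobilized spheroid acting as a flow obstacle
#'
#' The embedded cell aggregate is modeled as a rigid impermeable disk around
#' which the depth-averaged flow diverts. Default diameter 208 um.
#'
#' @param center Obstacle center, `c(x, y)` in micrometres.
#' @param diameter Obstacle diameter in micrometres.
#' @return An `obstacle_spec` list.
#' @export
obstacle_spec <- function(center = c(0, 0), diameter = 208) {
  if (diameter <= 0) abort("obstacle diameter must be positive",
                           class = "fiberflow_invalid_geometry")
  stopifnot(length(center) == 2, all(is.finite(center)))
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "obstacle_spec")
}

#' Depth-averaged flow model: uniform stream past a circular obstacle
#'
#' At the working flow rate the Reynolds number is far below one and the
#' channel is shallow, so the depth-averaged velocity is a potential flow.
#' Around a rigid disk this is the classical uniform stream + doublet
#' solution: far from the obstacle the flow is uniform with speed `U` along
#' -y, the normal velocity vanishes on the disk boundary, and the tangential
#' speed at the disk's sides reaches `2U`.
#'
#' The flow past the disk can be evaluated with either boundary condition on
#' the obstacle:
#' * `slip = "free"` (default): the classical potential solution (uniform
#'   stream + doublet), the exact depth-averaged Hele-Shaw limit; only the
#'   normal velocity vanishes at the disk.
#' * `slip = "no_slip"`: the analytic Brinkman solution. Depth-averaging the
#'   shallow-channel momentum equation leaves a drag term `12 mu u / h^2`,
#'   i.e. a Brinkman screening length `h / sqrt(12)` (~115 um for a 400 um
#'   channel); with no-slip on the disk the stream function is
#'   `U sin(theta) * (r + A/r + B K1(lambda r))`, producing a shear layer of
#'   that thickness around the obstacle. This variant drives the
#'   fiber-orientation synthesis, where the near-surface shear matters.
#'
#' @param geometry A [channel_geometry()].
#' @param obstacle An [obstacle_spec()]; must lie fully inside the channel.
#' @param slip Obstacle boundary condition, `"free"` or `"no_slip"`.
#' @return A `flow_model` list with fields `geometry`, `obstacle`, `U`
#'   (mean speed, um/s), `radius` (obstacle radius, um) and `slip`.
#' @export
flow_model <- function(geometry = channel_geometry(),
                       obstacle = obstacle_spec(),
                       slip = c("free", "no_slip")) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(obstacle, "obstacle_spec"))
  slip <- rlang::arg_match(slip)
  a <- obstacle$diameter / 2
  cx <- obstacle$center[1]; cy <- obstacle$center[2]
  if (abs(cx) + a > geometry$width / 2 || abs(cy) + a > geometry$length / 2) {
    abort("obstacle must lie fully inside the channel",
          class = "fiberflow_invalid_geometry")
  }
  model <- list(geometry = geometry, obstacle = obstacle,
                U = mean_inflow_speed(geometry), radius = a, slip = slip)
  if (slip == "no_slip") {
    # A, B from no-penetration f(a) = 0 and no-slip f'(a) = 0
    lambda <- sqrt(12) / geometry$height
    za <- lambda * a
    k1 <- besselK(za, 1)
    k1p <- -besselK(za, 0) - k1 / za
    M <- matrix(c(1 / a, -1 / a^2, k1, lambda * k1p), 2, 2)
    AB <- solve(M, c(-a, -1))
    model$brinkman <- list(lambda = lambda, A = AB[1], B = AB[2])
  }
  structure(model, class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> Hele-Shaw %s flow\n",
              if (identical(x$slip, "no_slip")) "Brinkman (no-slip)"
              else "potential (free-slip)"))
  cat(sprintf("  channel %.0f x %.0f x %.0f um, Q = %.3g ul/min, U = %.3f um/s\n",
              x$geometry$width, x$geometry$length, x$geometry$height,
              x$geometry$flow_rate, x$U))
  cat(sprintf("  obstacle r = %.1f um at (%.0f, %.0f), flow along -y\n",
              x$radius, x$obstacle$center[1], x$obstacle$center[2]))
  invisible(x)
}

# Brinkman (no-slip) fields in the lab frame at offsets dz from the obstacle
# center. In the frame with the stream along +x' (x' = -dy, y' = dx), the
# stream function is psi = U y' g(r) with g = f/r, f = r + A/r + B K1(l r);
# velocities are psi_y', -psi_x' and the velocity gradient is the Hessian of
# psi (traceless by construction). Rotated back to the lab frame.
brinkman_eval <- function(dz, model) {
  br <- model$brinkman
  U <- model$U
  lam <- br$lambda
  xp <- -Im(dz); yp <- Re(dz)
  r <- Mod(dz)
  z <- lam * r
  k0 <- besselK(z, 0); k1 <- besselK(z, 1)
  f <- r + br$A / r + br$B * k1
  fp <- 1 - br$A / r^2 + br$B * lam * (-k0 - k1 / z)
  fpp <- 2 * br$A / r^3 + br$B * lam^2 * (k1 * (1 + 2 / z^2) + k0 / z)
  g <- f / r
  G <- fp / r^2 - f / r^3          # g'/r
  Gp <- fpp / r^2 - 3 * fp / r^3 + 3 * f / r^4
  up <- U * (g + yp^2 * G)
  vp <- -U * xp * yp * G
  psixx <- U * yp * (G + xp^2 * Gp / r)
  psixy <- U * xp * (G + yp^2 * Gp / r)
  psiyy <- U * yp * (3 * G + yp^2 * Gp / r)
  # lab velocity (u, v) = (v', -u'); lab gradient = R L' R^T, R = [[0,1],[-1,0]]
  list(v = complex(real = vp, imaginary = -up),
       ux = -psixy, uy = psixx, vx = -psiyy, vy = psixy)
}

clamp_to_boundary <- function(dz, a, r) {
  inside <- r < a
  if (any(inside)) dz[inside] <- dz[inside] * (a / pmax(r[inside], 1e-12))
  dz
}

# complex velocity u + i v at complex positions z (lab frame).
# Free slip: w(z) = U e^{-i phi} (z - z0) + U e^{i phi} a^2/(z - z0),
# phi = -pi/2 (flow along -y); complex velocity u - i v = w'(z).
# If clamp, points inside the disk are evaluated at their radial projection
# onto the boundary (used by integrators so trajectories slide, not sink).
velocity_complex <- function(z, model, clamp = FALSE) {
  z0 <- complex(real = model$obstacle$center[1],
                imaginary = model$obstacle$center[2])
  a <- model$radius
  dz <- z - z0
  r <- Mod(dz)
  if (clamp) dz <- clamp_to_boundary(dz, a, r)
  if (identical(model$slip, "no_slip")) {
    return(brinkman_eval(dz, model)$v)
  }
  phi <- -pi / 2
  g <- model$U * exp(-1i * phi) - model$U * exp(1i * phi) * a^2 / dz^2
  Conj(g)
}

in_channel <- function(x, y, model) {
  abs(x) <= model$geometry$width / 2 & abs(y) <= model$geometry$length / 2
}

in_obstacle <- function(x, y, model, tol = 1e-9) {
  cx <- model$obstacle$center[1]; cy <- model$obstacle$center[2]
  sqrt((x - cx)^2 + (y - cy)^2) < model$radius * (1 - tol)
}

check_in_domain <- function(x, y, model) {
  if (any(!in_channel(x, y, model))) {
    abort("point outside the channel", class = "fiberflow_out_of_domain")
  }
  if (any(in_obstacle(x, y, model))) {
    abort("point inside the obstacle", class = "fiberflow_out_of_domain")
  }
  invisible(TRUE)
}

#' Evaluate the depth-averaged velocity field
#'
#' @param points A data frame with columns `x`, `y` (micrometres).
#' @param model A [flow_model()].
#' @return The input tibble with columns `vx`, `vy` (um/s) and `speed`
#'   appended.
#' @examples
#' m <- flow_model()
#' flow_velocity(tibble::tibble(x = c(0, 104), y = c(1000, 0)), m)
#' @export
flow_velocity <- function(points, model) {
  stopifnot(inherits(model, "flow_model"),
            all(c("x", "y") %in% names(points)))
  check_in_domain(points$x, points$y, model)
  v <- velocity_complex(complex(real = points$x, imaginary = points$y), model)
  as_tibble(points) |>
    mutate(vx = Re(v), vy = Im(v), speed = Mod(v))
}

#' Velocity-gradient tensor of the flow
#'
#' Analytic derivative of the potential-flow velocity. The returned tensor
#' `L[i, j] = d v_i / d x_j` is traceless (incompressibility) and symmetric
#' off-diagonal (irrotational flow); units 1/s.
#'
#' @param point Numeric `c(x, y)` in micrometres.
#' @param model A [flow_model()].
#' @return A 2x2 matrix.
#' @export
flow_velocity_gradient <- function(point, model) {
  stopifnot(inherits(model, "flow_model"), length(point) == 2)
  check_in_domain(point[1], point[2], model)
  g <- gradient_components(complex(real = point[1], imaginary = point[2]),
                           model)
  matrix(c(g$ux, g$vx, g$uy, g$vy), 2, 2)
}

# vectorized gradient components at complex z; for analytic g(z) = u - i v,
# g'(z) = u_x - i v_x, and Cauchy-Riemann gives u_y = v_x, v_y = -u_x.
gradient_components <- function(z, model, clamp = FALSE) {
  z0 <- complex(real = model$obstacle$center[1],
                imaginary = model$obstacle$center[2])
  a <- model$radius
  dz <- z - z0
  r <- Mod(dz)
  if (clamp) dz <- clamp_to_boundary(dz, a, r)
  if (identical(model$slip, "no_slip")) {
    b <- brinkman_eval(dz, model)
    return(b[c("ux", "vx", "uy", "vy")])
  }
  phi <- -pi / 2
  gp <- 2 * model$U * exp(1i * phi) * a^2 / dz^3
  list(ux = Re(gp), vx = -Im(gp), uy = -Im(gp), vy = -Re(gp))
}

#' Integrate a streamline of the flow
#'
#' Fourth-order fixed-step Runge-Kutta integration (via [deSolve::ode()],
#' method `"rk4"`) of `dx/dt = v(x)`. Points that would land inside the
#' obstacle are evaluated at their radial projection onto the boundary, so
#' streamlines slide along the disk instead of entering it.
#'
#' @param start Numeric `c(x, y)` in micrometres, inside the channel and
#'   outside the obstacle.
#' @param model A [flow_model()].
#' @param step Time step in seconds.
#' @param n_steps Number of steps.
#' @return A tibble with columns `t`, `x`, `y`.
#' @export
flow_streamline <- function(start, model, step = 5, n_steps = 400) {
  stopifnot(inherits(model, "flow_model"), length(start) == 2)
  check_in_domain(start[1], start[2], model)
  deriv <- function(t, state, parms) {
    v <- velocity_complex(complex(real = state[1], imaginary = state[2]),
                          model, clamp = TRUE)
    list(c(Re(v), Im(v)))
  }
  times <- seq(0, step * n_steps, by = step)
  sol <- deSolve::ode(y = c(x = start[1], y = start[2]), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  keep <- in_channel(sol[, "x"], sol[, "y"], model)
  tibble(t = sol[keep, "time"], x = sol[keep, "x"], y = sol[keep, "y"])
}

#' Tabulate the velocity field on a regular grid
#'
#' Convenience export for plotting or PIV-style comparison: evaluates the
#' velocity on a regular grid, skipping points inside the obstacle.
#'
#' @param model A [flow_model()].
#' @param xlim,ylim Ranges in micrometres.
#' @param n Grid points per axis.
#' @return A tibble with `x`, `y`, `vx`, `vy`, `speed`.
#' @export
flow_field_table <- function(model, xlim = c(-500, 500), ylim = c(-500, 500),
                             n = 41) {
  pts <- expand_grid(x = seq(xlim[1], xlim[2], length.out = n),
                     y = seq(ylim[1], ylim[2], length.out = n)) |>
    filter(!in_obstacle(.data$x, .data$y, model))
  flow_velocity(pts, model)
}
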