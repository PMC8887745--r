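test_that("mean inflow speed converts flow rate to depth-averaged speed", {
  # 0.2 ul/min = 0.2 mm^3/min; / (3.8 mm x 0.4 mm) / 60 s = 2.193 um/s
  expect_equal(mean_inflow_speed(channel_geometry()), 0.2e9 / 60 / (3800 * 400))
  expect_equal(mean_inflow_speed(channel_geometry()), 2.193, tolerance = 1e-3)
  expect_equal(mean_inflow_speed(channel_geometry(flow_rate = 0)), 0)
  expect_equal(mean_inflow_speed(channel_geometry(flow_rate = 0.4)),
               2 * mean_inflow_speed(channel_geometry(flow_rate = 0.2)))
})

test_that("invalid geometry is rejected", {
  expect_error(channel_geometry(width = -1), class = "fiberflow_invalid_geometry")
  expect_error(channel_geometry(height = 5000), class = "fiberflow_invalid_geometry")
  expect_error(obstacle_spec(diameter = 0), class = "fiberflow_invalid_geometry")
  expect_error(flow_model(obstacle = obstacle_spec(center = c(1800, 0))),
               class = "fiberflow_invalid_geometry")
})

test_that("potential flow has stagnation points, 2U side speed, uniform far field", {
  m <- flow_model()
  a <- m$radius
  stag <- flow_velocity(tibble::tibble(x = c(0, 0), y = c(a, -a)), m)
  expect_lt(max(stag$speed), 1e-12)
  side <- flow_velocity(tibble::tibble(x = c(a, -a), y = c(0, 0)), m)
  expect_equal(side$speed, rep(2 * m$U, 2), tolerance = 1e-12)
  expect_equal(side$vy, rep(-2 * m$U, 2), tolerance = 1e-12)
  far <- flow_velocity(tibble::tibble(x = c(0, 500), y = c(20 * a, -20 * a)), m)
  expect_lt(max(abs(far$speed - m$U)) / m$U, 0.01)
  expect_lt(max(abs(far$vx)) / m$U, 0.01)
})

test_that("velocity evaluation rejects out-of-domain points", {
  m <- flow_model()
  expect_error(flow_velocity(tibble::tibble(x = 0, y = 0), m),
               class = "fiberflow_out_of_domain")
  expect_error(flow_velocity(tibble::tibble(x = 50, y = 50), m),
               class = "fiberflow_out_of_domain")
  expect_error(flow_velocity(tibble::tibble(x = 3000, y = 0), m),
               class = "fiberflow_out_of_domain")
  expect_error(flow_velocity_gradient(c(0, 0), m),
               class = "fiberflow_out_of_domain")
})

test_that("analytic velocity gradient matches finite differences (both slips)", {
  for (slip in c("free", "no_slip")) {
    m <- flow_model(slip = slip)
    a <- m$radius
    withr::with_seed(11, {
      worst <- 0
      for (k in 1:100) {
        r <- runif(1, 1.2 * a, 8 * a); th <- runif(1, 0, 2 * pi)
        p <- c(r * cos(th), r * sin(th))
        L <- flow_velocity_gradient(p, m)
        Lfd <- fd_velocity_gradient(p, m, h = 0.25)
        worst <- max(worst, max(abs(L - Lfd)) / max(max(abs(L)), 1e-12))
        expect_lt(abs(sum(diag(L))), 1e-9 * max(abs(L)) + 1e-300)
      }
      expect_lt(worst, 1e-4)  # second-order FD at h = 0.25 um
    })
  }
})

test_that("gradient vanishes in the far field", {
  m <- flow_model()
  L <- flow_velocity_gradient(c(0, 30 * m$radius), m)
  # doublet gradient decays as 2 U a^2 / r^3
  expect_lt(max(abs(L)), 2 * m$U * m$radius^2 / (30 * m$radius)^3 * 1.01)
})

test_that("mass flux through cross-channel stations is conserved", {
  m <- flow_model()
  a <- m$radius
  w <- m$geometry$width
  xs <- seq(-w / 2 + 1, w / 2 - 1, length.out = 4001)
  for (y0 in c(3 * a, -3 * a, 8 * a)) {
    v <- flow_velocity(tibble::tibble(x = xs, y = y0), m)
    flux <- sum(-v$vy) * (xs[2] - xs[1])
    expect_equal(flux / (m$U * (xs[length(xs)] - xs[1])), 1, tolerance = 5e-3)
  }
})

test_that("flow is mirror-symmetric about the flow axis", {
  m <- flow_model()
  pts <- tibble::tibble(x = c(50, 130, 300), y = c(200, -80, 40))
  v1 <- flow_velocity(pts, m)
  v2 <- flow_velocity(dplyr::mutate(pts, x = -x), m)
  expect_equal(v1$vy, v2$vy, tolerance = 1e-12)
  expect_equal(v1$vx, -v2$vx, tolerance = 1e-12)
})

test_that("no-slip variant kills the velocity at the disk surface", {
  m <- flow_model(slip = "no_slip")
  a <- m$radius
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  v <- flow_velocity(tibble::tibble(x = (a + 0.01) * cos(th),
                                    y = (a + 0.01) * sin(th)), m)
  expect_lt(max(v$speed), 1e-3 * m$U)
  far <- flow_velocity(tibble::tibble(x = 0, y = -30 * a), m)
  expect_equal(far$vy, -m$U, tolerance = 0.01)
})

test_that("streamlines avoid the obstacle and respect symmetry", {
  m <- flow_model()
  a <- m$radius
  # lateral far start: nearly straight, parallel to flow
  s1 <- flow_streamline(c(1500, 5000), m, step = 20, n_steps = 100)
  expect_lt(diff(range(s1$x)), 10)
  expect_lt(max(s1$y[-1] - s1$y[-nrow(s1)]), 0)
  # straddling starts: mirror images, never inside the disk
  s2 <- flow_streamline(c(30, 600), m, step = 10, n_steps = 200)
  s3 <- flow_streamline(c(-30, 600), m, step = 10, n_steps = 200)
  expect_equal(s2$x, -s3$x, tolerance = 1e-10)
  expect_equal(s2$y, s3$y, tolerance = 1e-10)
  expect_gte(min(sqrt(s2$x^2 + s2$y^2)), a * (1 - 1e-6))
  # on-axis start decelerates into the stagnation point and stalls there
  s4 <- flow_streamline(c(0, 500), m, step = 10, n_steps = 40)
  expect_gte(min(sqrt(s4$x^2 + s4$y^2)), a * (1 - 1e-6))
  expect_lt(abs(tail(s4$y, 1) - a), 2)
  v_end <- flow_velocity(tail(s4, 1)[, c("x", "y")], m)
  expect_lt(v_end$speed, 0.05 * m$U)
  expect_error(flow_streamline(c(0, 0), m), class = "fiberflow_out_of_domain")
})

test_that("divergence sampled by finite differences is negligible", {
  m <- flow_model()
  h <- 0.05
  withr::with_seed(3, {
    for (k in 1:25) {
      r <- runif(1, 1.3 * m$radius, 6 * m$radius); th <- runif(1, 0, 2 * pi)
      p <- c(r * cos(th), r * sin(th))
      vx <- flow_velocity(tibble::tibble(x = p[1] + c(h, -h), y = rep(p[2], 2)), m)
      vy <- flow_velocity(tibble::tibble(x = rep(p[1], 2), y = p[2] + c(h, -h)), m)
      div <- (vx$vx[1] - vx$vx[2]) / (2 * h) + (vy$vy[1] - vy$vy[2]) / (2 * h)
      expect_lt(abs(div), 1e-8 * m$U)
    }
  })
})
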