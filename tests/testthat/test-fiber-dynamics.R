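test_that("slender-rod rotation rate has the classical limits", {
  # solid-body rotation at omega turns every rod at omega
  omega <- 0.1
  L_rot <- matrix(c(0, omega, -omega, 0), 2, 2)
  for (th in c(0, 37, 90, 135)) {
    expect_equal(rod_rotation_rate(th, L_rot), omega * 180 / pi,
                 tolerance = 1e-12)
  }
  expect_equal(rod_rotation_rate(45, matrix(0, 2, 2)), 0)
  # simple shear u_x = g*y: flow-aligned rod is a fixed point
  L_shear <- matrix(c(0, 0, 0.3, 0), 2, 2)
  expect_equal(rod_rotation_rate(0, L_shear), 0)
  # planar extension along x rotates rods toward the extensional axis
  L_ext <- matrix(c(0.1, 0, 0, -0.1), 2, 2)
  expect_lt(rod_rotation_rate(45, L_ext), 0)   # toward 0
  expect_gt(rod_rotation_rate(135, L_ext), 0)  # toward 180
})

test_that("rod in uniform far-field flow translates without rotating", {
  m <- flow_model()
  tr <- advect_rod(list(x = 1500, y = 8000, theta = 57), m,
                   dt = 5, t_max = 200)
  expect_lt(max(abs(tr$theta - 57)), 0.01)
  expect_equal(tail(tr$y, 1) - tr$y[1], -m$U * 200, tolerance = 0.01)
  expect_lt(abs(tail(tr$x, 1) - 1500), 0.1)
  expect_error(advect_rod(list(x = 0, y = 0, theta = 0), m),
               class = "fiberflow_out_of_domain")
})

test_that("advected rods reproduce the flow-derived orientation pattern", {
  m <- flow_model()
  a <- m$radius
  tr <- advect_rod(list(x = 1, y = 500, theta = 91), m, dt = 2, t_max = 4000)
  expect_gte(min(sqrt(tr$x^2 + tr$y^2)), a * (1 - 1e-6)) # never penetrates
  # upstream face: perpendicular to flow (0/180)
  up <- dplyr::filter(tr, y > a, y < a + 40, abs(x) < a)
  expect_gt(nrow(up), 0)
  expect_lt(min(axial_diff(up$theta, 0)), 15)
  # alongside: tangential to the disk
  side <- dplyr::filter(tr, sqrt(x^2 + y^2) < a + 15, abs(y) < a)
  tang <- wrap_axial(atan2(side$y, side$x) * 180 / pi + 90)
  expect_lt(max(axial_diff(side$theta, tang)), 15)
  # downstream: back to the flow axis
  dn <- dplyr::filter(tr, y < -1.5 * a, y > -4 * a)
  expect_lt(max(axial_diff(dn$theta, 90)), 15)
  # angles remain valid axial angles throughout
  expect_true(all(tr$theta >= 0 & tr$theta < 180))
})

test_that("synthesized orientation field is deterministic and mirror-symmetric", {
  m <- flow_model(slip = "no_slip")
  spec <- grid_spec(c(-412, 412), c(-412, 412))
  g1 <- synthesize_orientation_field(m, spec, seed = 5)
  g2 <- synthesize_orientation_field(m, spec, seed = 5)
  expect_identical(g1$alpha, g2$alpha)
  # symmetric seeding (no jitter): field mirrors about the flow axis
  gs <- synthesize_orientation_field(m, spec, angle_jitter_sd = 0, seed = 1)
  df <- as.data.frame(dplyr::filter(gs, !filled))
  mir <- dplyr::left_join(df,
    dplyr::mutate(df, x = -x) |> dplyr::select(x, y, alpha_m = alpha),
    by = c("x", "y"))
  expect_lt(max(axial_diff(mir$alpha, 180 - mir$alpha_m)), 1e-6)
})

test_that("flow-derived field shows the observed orientation regions", {
  # default obstacle (aggregate d = 208 um), spheroid-anchored grid
  m <- flow_model(slip = "no_slip")
  a <- m$radius
  spec <- grid_spec_for_spheroid(a)
  g <- synthesize_orientation_field(m, spec, seed = 1)
  df <- as.data.frame(g)
  r <- sqrt(df$x^2 + df$y^2)
  # far field: flow-aligned within 5 degrees
  far <- df[r > 10 * a, ]
  expect_lt(max(axial_diff(far$alpha, 90)), 5)
  # upstream face box: perpendicular to flow within 20 degrees
  up <- df[abs(df$x) < 103 & df$y > a - 52 & df$y < a + 52, ]
  expect_gt(nrow(up), 0)
  expect_lt(min(axial_diff(up$alpha, 0)), 20)
  # downstream face box: radial (flow-aligned) within 20 degrees
  dn <- df[abs(df$x) < 60 & df$y < -a - 52 & df$y > -a - 160, ]
  expect_gt(nrow(dn), 0)
  expect_lt(min(axial_diff(dn$alpha, 90)), 20)
  # tangential ring around the spheroid
  ring <- df[r > a & r < a + 115, ]
  tang <- axial_diff(ring$alpha,
                     wrap_axial(atan2(ring$y, ring$x) * 180 / pi + 90))
  expect_lt(median(tang), 20)
})

test_that("canonical fields have their defining geometry", {
  spec <- grid_spec(c(-360.5, 360.5), c(-360.5, 360.5))
  gu <- canonical_field("uniform", spec, angle = 90)
  expect_true(all(gu$alpha == 90))
  gr <- canonical_field("radial", spec)
  south <- grid_angle_at(gr, 0, -309)   # box center due south
  expect_lt(axial_diff(south, 90), 1e-10)
  east <- grid_angle_at(gr, 309, 0)
  expect_lt(axial_diff(east, 0), 1e-10)
  gt <- canonical_field("tangential", spec)
  expect_lt(max(axial_diff(gt$alpha, gr$alpha + 90)), 1e-10)
  # isotropic: pooled angles close to uniform -> alignment degree near 1
  gi <- canonical_field("isotropic", grid_spec(c(-2060, 2060), c(-2060, 2060)),
                        seed = 3)
  hist <- tibble::tibble(angle = 0:179,
                         weight = tabulate(floor(gi$alpha) + 1, 180))
  expect_equal(suppressMessages(degree_of_alignment(hist)), 1,
               tolerance = 0.1)
  expect_error(canonical_field("swirl", spec))
})
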