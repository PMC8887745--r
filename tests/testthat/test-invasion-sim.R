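test_that("per-step sizes follow the diffusive normalization", {
  k <- step_sizes(220, 0, 100)
  expect_equal(k$k_p, 22)
  expect_equal(k$k_v, 0)
  expect_equal(step_sizes(0, 0, 50)$k_p, 0)
  expect_equal(step_sizes(150, 60, 1)$k_p, 150)
  expect_equal(step_sizes(150, 60, 1)$k_v, 60)
  expect_equal(step_sizes(220, 0, 100, "linear")$k_p, 2.2)
  expect_error(step_sizes(220, 0, 0))
})

test_that("cell seeding matches the requested geometry and is reproducible", {
  cfg_b <- sim_config(n_cells = 500, radius = 150, seeding = "boundary",
                      seed = 3)
  cells <- seed_cells(cfg_b)
  expect_equal(sqrt(cells$x^2 + cells$y^2), rep(150, 500), tolerance = 1e-12)
  cfg_d <- sim_config(n_cells = 4000, radius = 150, seeding = "disk", seed = 3)
  disk <- seed_cells(cfg_d)
  expect_equal(mean(sqrt(disk$x^2 + disk$y^2)), 2 / 3 * 150, tolerance = 0.02)
  expect_identical(seed_cells(cfg_d), seed_cells(cfg_d))
  one <- seed_cells(sim_config(n_cells = 1, radius = 10))
  expect_identical(nrow(one), 1L)
})

test_that("walk steps move along the local fiber axis as specified", {
  k <- list(k_p = 22, k_v = 0)
  frame <- tibble::tibble(x = rep(0, 2000), y = rep(0, 2000))
  withr::with_seed(1, {
    # alpha = 90, k_v = 0: all displacement is vertical in steps of 22
    nxt <- walk_step(frame, rep(90, 2000), k)
    expect_lt(max(abs(nxt$x)), 1e-12)
    expect_true(all(nxt$y %in% c(-22, 0, 22)))
    # roughly a quarter of cells take each of the four moves
    expect_equal(mean(nxt$y == 22), 0.25, tolerance = 0.05)
    # alpha = 0: parallel moves shift x by +-k_p
    nxt0 <- walk_step(frame, rep(0, 2000), k)
    expect_lt(max(abs(nxt0$y)), 1e-12)
    expect_true(all(nxt0$x %in% c(-22, 0, 22)))
    # isotropic steps: mean squared displacement per step is k^2
    kk <- list(k_p = 10, k_v = 10)
    nxt2 <- walk_step(frame, runif(2000, 0, 180), kk)
    expect_equal(mean(nxt2$x^2 + nxt2$y^2), 100, tolerance = 0.01)
  })
})

test_that("simulation conserves cells, is static at zero step, reproducible", {
  g <- canonical_field("uniform", grid_spec(c(-515, 515), c(-515, 515)))
  cfg0 <- sim_config(r_p = 0, r_v = 0, n_steps = 20, days = 2, n_cells = 50,
                     radius = 100, seed = 2)
  sim0 <- simulate_invasion(g, cfg0)
  pos <- sim0$positions
  expect_equal(unique(table(pos$day)), 50L)
  d0 <- dplyr::filter(pos, day == 0)
  d2 <- dplyr::filter(pos, day == 2)
  expect_equal(d2$x, d0$x)
  expect_equal(d2$y, d0$y)
  expect_equal(d0[, c("x", "y")], seed_cells(cfg0)[, c("x", "y")])
  cfg <- sim_config(n_cells = 100, days = 1, seed = 9)
  expect_identical(simulate_invasion(g, cfg)$positions,
                   simulate_invasion(g, cfg)$positions)
})

test_that("on a fine radial field with no cross-fiber steps motion is radial", {
  spec <- grid_spec(c(-824, 824), c(-824, 824), box_size = 10)
  g <- canonical_field("radial", spec)
  cfg <- sim_config(r_p = 40, r_v = 0, n_steps = 50, days = 2, n_cells = 200,
                    radius = 150, seeding = "boundary", seed = 4)
  sim <- simulate_invasion(g, cfg)
  pol <- sim$positions |>
    dplyr::mutate(pol = atan2(y, x) * 180 / pi) |>
    tidyr::pivot_wider(id_cols = "cell", names_from = "day",
                       values_from = "pol")
  drift <- axial_diff(pol$`2`, pol$`0`)
  # residual drift comes from the box-wise quantization of the field
  expect_lt(max(drift), 6)
})

test_that("isotropic steps give isotropic dispersal", {
  g <- canonical_field("isotropic", grid_spec(c(-2060, 2060), c(-2060, 2060)),
                       seed = 5)
  cfg <- sim_config(r_p = 150, r_v = 150, n_steps = 100, days = 1,
                    n_cells = 3000, radius = 100, seed = 6)
  sim <- simulate_invasion(g, cfg)
  disp <- dplyr::left_join(
    dplyr::filter(sim$positions, day == 1),
    dplyr::filter(sim$positions, day == 0),
    by = "cell", suffix = c("", "0"))
  msd_ratio <- mean((disp$x - disp$x0)^2) / mean((disp$y - disp$y0)^2)
  expect_equal(msd_ratio, 1, tolerance = 0.1)
})

test_that("day-1 statistics are insensitive to the number of steps per day", {
  g <- canonical_field("radial", grid_spec(c(-824, 824), c(-824, 824),
                                           box_size = 10))
  rms <- sapply(c(25, 100, 400), function(N) {
    cfg <- sim_config(r_p = 220, r_v = 0, n_steps = N, days = 1,
                      n_cells = 1500, radius = 150, seeding = "boundary",
                      seed = 11)
    sim <- simulate_invasion(g, cfg)
    disp <- dplyr::left_join(dplyr::filter(sim$positions, day == 1),
                             dplyr::filter(sim$positions, day == 0),
                             by = "cell", suffix = c("", "0"))
    sqrt(mean((disp$x - disp$x0)^2 + (disp$y - disp$y0)^2))
  })
  # diffusive scaling: RMS displacement ~ r_p/sqrt(2) regardless of N
  expect_equal(rms[1], rms[2], tolerance = 0.05)
  expect_equal(rms[2], rms[3], tolerance = 0.05)
  expect_equal(rms[2], 220 / sqrt(2), tolerance = 0.05)
})

test_that("the day-scale parallel step is recovered from simulated dispersal", {
  g <- canonical_field("uniform", grid_spec(c(-515, 515), c(-515, 515)),
                       angle = 90)
  est <- sapply(1:20, function(s) {
    cfg <- sim_config(r_p = 220, r_v = 0, n_steps = 100, days = 1,
                      n_cells = 400, radius = 100, seed = 100 + s)
    sim <- simulate_invasion(g, cfg)
    disp <- dplyr::left_join(dplyr::filter(sim$positions, day == 1),
                             dplyr::filter(sim$positions, day == 0),
                             by = "cell", suffix = c("", "0"))
    # along-fiber (y) variance = k_p^2 N/2 = r_p^2/2
    sqrt(2 * mean((disp$y - disp$y0)^2))
  })
  ci <- mean(est) + c(-2, 2) * sd(est) / sqrt(length(est))
  expect_gt(220, ci[1])
  expect_lt(220, ci[2])
  expect_lt(max(abs(est - 220)) / 220, 0.1)
})
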