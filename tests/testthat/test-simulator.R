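free_params <- function() swarm_params(gamma = 0, scale = 1, gain = 0)

test_that("a force-free insect drifts in a straight line", {
  v0 <- c(0.6, -0.3, 0.2)
  cfg <- sim_config(n_insects = 1, dt = 0.1, n_frames = 40, box = 100,
                    boundary_mode = "none", params = free_params(),
                    noise = noise_spec("curl", gain = 0),
                    init_positions = rbind(c(50, 50, 50)),
                    init_velocities = rbind(v0), seed = 1)
  tr <- simulate_swarm(cfg)
  for (t in 1:40)
    expect_equal(tr$positions[t, 1, ], c(50, 50, 50) + (t - 1) * 0.1 * v0,
                 tolerance = 1e-10)
})

test_that("friction alone decays the speed toward zero", {
  p <- swarm_params(gamma = 2, scale = 1, gain = 0)
  cfg <- sim_config(n_insects = 1, dt = 0.05, n_frames = 60, box = 100,
                    boundary_mode = "none", params = p,
                    noise = noise_spec("curl", gain = 0),
                    init_positions = rbind(c(50, 50, 50)),
                    init_velocities = rbind(c(2, 0, 0)), seed = 1)
  tr <- simulate_swarm(cfg)
  sp <- sqrt(rowSums((tr$positions[-1, 1, , drop = FALSE] -
                      tr$positions[-60, 1, , drop = FALSE])[, 1, ]^2)) / 0.05
  expect_true(all(diff(sp) < 0))
  # numeric oracle for dv/dt = -gamma v^2 (explicit Euler, same scheme)
  v <- 2
  for (k in 1:59) v <- v + (-2 * v * v) * 0.05
  expect_equal(sp[59], v, tolerance = 1e-8)
})

test_that("one Euler step matches the hand-evaluated update for a resting pair", {
  p <- swarm_params(chi_rep = 5, r_rep = 1, chi_ali = 0, r_ali = 1,
                    chi_att = 0, r_att = 3)
  dt <- 0.05
  cfg <- sim_config(n_insects = 2, dt = dt, n_frames = 2, box = 10,
                    boundary_mode = "none", params = p,
                    noise = noise_spec("curl", gain = 0),
                    init_positions = rbind(c(4.8, 5, 5), c(5.2, 5, 5)),
                    seed = 1)
  tr <- simulate_swarm(cfg)
  # hand Euler: F = chi_rep away from the other; v_pref = F*dt; r += v*dt
  expect_equal(tr$positions[2, 1, ], c(4.8, 5, 5) + c(-5 * dt, 0, 0) * dt,
               tolerance = 1e-10)
  expect_equal(tr$positions[2, 2, ], c(5.2, 5, 5) + c(5 * dt, 0, 0) * dt,
               tolerance = 1e-10)
  sep0 <- 0.4
  sep1 <- sqrt(sum((tr$positions[2, 1, ] - tr$positions[2, 2, ])^2))
  expect_gt(sep1, sep0)
})

test_that("trajectories are deterministic in (config, seed) and n_frames=1 is the initial state", {
  cfg <- build_scenario("midge_box", n_insects = 20, n_frames = 40, seed = 9)
  t1 <- simulate_swarm(cfg)
  t2 <- simulate_swarm(cfg)
  expect_identical(t1$positions, t2$positions)
  cfg2 <- build_scenario("midge_box", n_insects = 20, n_frames = 40, seed = 10)
  expect_false(identical(t1$positions, simulate_swarm(cfg2)$positions))
  cfg1 <- build_scenario("midge_box", n_insects = 5, n_frames = 1, seed = 9)
  tr <- simulate_swarm(cfg1)
  expect_equal(dim(tr$positions), c(1, 5, 3))
})

test_that("reflecting boundaries keep every insect inside the box", {
  cfg <- build_scenario("midge_box", n_insects = 30, n_frames = 150, seed = 4)
  tr <- simulate_swarm(cfg)
  expect_true(all(tr$positions >= 0 & tr$positions <= 20))
})

test_that("scenario builder reproduces the published parameter columns", {
  esc <- build_scenario("escape")
  expect_equal(esc$params$chi_res, 20.0)
  expect_equal(esc$params$r_res, 8.0)
  expect_equal(esc$params$r_rep, 0.2)
  expect_equal(esc$params$r_ali, 10.2)    # 0.2 + 10.0
  expect_equal(esc$params$r_att, 19.4)    # 10.2 + 9.2
  expect_equal(esc$stimuli[[1]]$s_e, 1L)

  mig <- build_scenario("migration")
  expect_equal(mig$n_insects, 2000L)
  expect_equal(mig$box[2, ] - mig$box[1, ], c(24, 5, 0.5))
  expect_equal(mig$boundary_mode, "none")
  expect_equal(mig$stimuli[[1]]$s_e, 0L)

  mid <- build_scenario("midge_box", n_insects = 1)
  expect_equal(mid$n_insects, 1L)
  expect_equal(mid$params$gamma, 11.16)
  expect_equal(mid$params$r_att, 0.17 + 0 + 5.12)

  pt <- build_scenario("phase_transition")
  expect_named(pt$schedule, c("gain", "chi_ali"))
  expect_equal(pt$schedule$gain[2], 0)
  expect_gt(pt$schedule$chi_ali[2], pt$schedule$chi_ali[1])

  expect_error(build_scenario("termite_mound"), "unknown scenario")

  # every scenario constructs and runs, including moving stimuli and obstacles
  for (nm in c("midge_box", "aggregation", "fruitfly", "migration",
               "mate_competition", "phase_transition", "phototaxis",
               "escape", "bats")) {
    tr <- simulate_swarm(build_scenario(nm, n_insects = 5, n_frames = 3,
                                        seed = 1))
    expect_equal(dim(tr$positions), c(3, 5, 3))
  }
})

test_that("schedule ramps parameters linearly across the run", {
  cfg <- sim_config(n_insects = 2, n_frames = 101, params = free_params(),
                    schedule = list(gain = c(1, 0), chi_ali = c(0, 10)))
  p1 <- swarmsim:::scheduled_params(cfg, 1)
  p51 <- swarmsim:::scheduled_params(cfg, 51)
  p101 <- swarmsim:::scheduled_params(cfg, 101)
  expect_equal(c(p1$gain, p51$gain, p101$gain), c(1, 0.5, 0))
  expect_equal(c(p1$chi_ali, p51$chi_ali, p101$chi_ali), c(0, 5, 10))
})

test_that("temperature-density polynomial is clamped, peaked near 22C, and symmetric", {
  expect_warning(n0 <- temperature_to_density(0), "clamped")
  expect_equal(n0, 0)
  t_star <- 4.7643 / (2 * 0.1073)
  ts <- seq(9, 35, by = 0.25)    # inside the positive root interval
  expect_true(all(temperature_to_density(t_star) >= temperature_to_density(ts)))
  expect_equal(t_star, 22.2, tolerance = 0.01)
  # parabola symmetry about the vertex
  expect_equal(temperature_to_density(t_star + 3),
               temperature_to_density(t_star - 3), tolerance = 1e-9)
})

test_that("density uses the fixed-reference-volume convention", {
  mk <- function(n) swarm_trajectory(array(runif(2 * n * 3), c(2, n, 3)), 1)
  v0 <- 500 / 9469.7
  expect_equal(measure_density(mk(500), v0)[1], 9469.7)
  expect_equal(measure_density(mk(30), v0)[1], 30 / v0)
  expect_error(measure_density(mk(3), 0), "> 0")
})

test_that("trajectory text files round-trip losslessly and report malformed rows", {
  set.seed(6)
  tr <- swarm_trajectory(array(rnorm(2 * 2 * 3), c(2, 2, 3)), dt = 1 / 60)
  path <- tempfile(fileext = ".txt")
  write_trajectory(tr, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2 + 4)     # dt comment + header + 4 data rows
  back <- read_trajectory(path)
  expect_identical(back$positions, tr$positions)
  expect_equal(back$dt, tr$dt)
  # a row with a missing coordinate is reported with its line number
  bad <- lines
  bad[4] <- paste(strsplit(bad[4], " ")[[1]][1:4], collapse = " ")
  badpath <- tempfile(fileext = ".txt")
  writeLines(bad, badpath)
  expect_error(read_trajectory(badpath), "line 4")
})

test_that("escape scenario: responders flee the predator, swarm regroups after", {
  cfg <- build_scenario("escape", n_insects = 60, n_frames = 200, seed = 5)
  pred_pos <- c(10, 10, 10)
  cfg$stimuli <- list(stimulus(pred_pos, "predator", from = 2, to = 120))
  tr <- simulate_swarm(cfg)
  p <- tr$positions
  d1 <- sqrt(colSums((t(p[1, , ]) - pred_pos)^2))
  responders <- which(d1 <= cfg$params$r_res)
  expect_gt(length(responders), 5)
  dmean <- sapply(1:51, function(t)
    mean(sqrt(colSums((t(p[t, responders, ]) - pred_pos)^2))))
  expect_true(all(diff(dmean) > 0))      # monotone flight within 50 frames
  radius <- function(t) {
    c0 <- colMeans(p[t, , ])
    mean(sqrt(colSums((t(p[t, , ]) - c0)^2)))
  }
  expect_lt(radius(200), radius(120))    # contraction after deactivation
})

test_that("gain-down/alignment-up schedule drives a disorder-to-order transition", {
  cfg <- build_scenario("phase_transition", n_insects = 60, n_frames = 400,
                        seed = 2)
  pol <- trajectory_polarization(simulate_swarm(cfg))
  k <- length(pol)
  expect_lt(mean(pol[1:40], na.rm = TRUE), 0.3)
  expect_gt(mean(pol[(k - 39):k], na.rm = TRUE), 0.7)
})

test_that("aggregation swarm centre wanders little relative to the swarm radius", {
  cfg <- build_scenario("aggregation", n_insects = 80, n_frames = 250, seed = 3)
  tr <- simulate_swarm(cfg)
  p <- tr$positions
  centres <- t(sapply(1:250, function(t) colMeans(p[t, , ])))
  steps <- sqrt(rowSums(diff(centres)^2))
  radius <- mean(sapply(seq(10, 250, by = 20), function(t) {
    c0 <- colMeans(p[t, , ])
    mean(sqrt(colSums((t(p[t, , ]) - c0)^2)))
  }))
  expect_lt(max(steps), 0.1 * radius)
})

test_that("white noise produces rougher trajectories than curl noise at matched gain", {
  jerk_var <- function(kind) {
    cfg <- sim_config(n_insects = 25, n_frames = 150, box = 10,
                      params = swarm_params(gamma = 2, scale = 1, gain = 2,
                                            chi_rep = 2, r_rep = 0.3,
                                            chi_att = 6, r_att = 4,
                                            r_ali = 0.3),
                      noise = noise_spec(kind, seed = 31), seed = 31)
    var(compute_metric("mu", simulate_swarm(cfg))$values)
  }
  expect_gt(jerk_var("white"), jerk_var("curl"))
})
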