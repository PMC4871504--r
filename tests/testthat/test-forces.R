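test_that("zone indicator partitions [0, r_att] with half-open inner bounds", {
  p <- swarm_params(chi_rep = 1, r_rep = 2, chi_ali = 1, r_ali = 5,
                    chi_att = 1, r_att = 9)
  expect_identical(zone_indicator(1, p), -1L)      # r_rep/2
  expect_identical(zone_indicator(2, p), 0L)       # x == r_rep
  expect_identical(zone_indicator(5, p), 1L)       # x == r_ali
  expect_identical(zone_indicator(9, p), 1L)       # x == r_att (closed)
  expect_error(zone_indicator(9.1, p), "beyond r_att")
  expect_error(zone_indicator(-1, p), ">= 0")
  # exactly one zone applies, and g is monotone non-decreasing
  xs <- seq(0, 9, length.out = 200)
  g <- zone_indicator(xs, p)
  expect_true(all(g %in% c(-1L, 0L, 1L)))
  expect_true(all(diff(g) >= 0))
})

test_that("neighbour sets use the r_att cutoff and exclude the focal insect", {
  r <- 2
  pos <- rbind(c(0, 0, 0), c(1.5 * r, 0, 0))
  expect_length(neighbor_indices(pos, 1, r), 0)
  pos2 <- rbind(c(0, 0, 0), c(0.5 * r, 0, 0))
  expect_identical(neighbor_indices(pos2, 1, r), 2L)
  # 5 agents on a line with spacing r_att: middle agent sees exactly 2
  line <- cbind((0:4) * r, 0, 0)
  nb <- neighbor_indices(line, 3, r)
  ref <- which(sqrt(colSums((t(line) - line[3, ])^2)) <= r & seq_len(5) != 3)
  expect_setequal(nb, ref)
  expect_length(nb, 2)
  expect_false(3 %in% neighbor_indices(line, 3, 10 * r))
})

test_that("two resting insects in the repulsion zone push straight apart", {
  p <- swarm_params(chi_rep = 2, r_rep = 1, chi_ali = 0, r_ali = 1,
                    chi_att = 0, r_att = 3)
  pos <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  vel <- matrix(0, 2, 3)
  f1 <- interaction_force(1, pos, vel, p)
  f2 <- interaction_force(2, pos, vel, p)
  expect_equal(f1, -f2)
  expect_equal(f1, c(-2, 0, 0))            # magnitude chi_rep, away from 2
  expect_equal(sqrt(sum(f1^2)), p$chi_rep)
})

test_that("interaction force on a three-insect toy matches term-by-term evaluation", {
  p <- swarm_params(chi_rep = 2, r_rep = 1, chi_ali = 3, r_ali = 2,
                    chi_att = 4, r_att = 4)
  pos <- rbind(c(0, 0, 0),        # focal
               c(0.5, 0, 0),      # repulsion zone
               c(0, 3, 0))        # attraction zone
  vel <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  # hand evaluation: rep neighbour at distance 0.5 -> -chi_rep * (1,0,0);
  # att neighbour at distance 3 -> +chi_att * (0,1,0); no alignment neighbour
  expected <- 2 * c(-1, 0, 0) + 4 * c(0, 1, 0)
  expect_equal(interaction_force(1, pos, vel, p), expected, tolerance = 1e-12)

  # alignment-only configuration: velocity-matching term
  pos2 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  vel2 <- rbind(c(0, 0, 0), c(0, 2, 0))
  expect_equal(interaction_force(1, pos2, vel2, p), 3 * c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("isolated insect feels no interaction force", {
  p <- swarm_params(chi_rep = 1, r_rep = 1, chi_ali = 1, r_ali = 2,
                    chi_att = 1, r_att = 3)
  pos <- rbind(c(0, 0, 0), c(10, 0, 0))
  vel <- matrix(0, 2, 3)
  expect_equal(interaction_force(1, pos, vel, p), c(0, 0, 0))
})

test_that("interaction force matches the brute-force double-loop oracle", {
  p <- swarm_params(gamma = 0, chi_rep = 2.3, r_rep = 0.6, chi_ali = 1.1,
                    r_ali = 1.4, chi_att = 3.7, r_att = 2.5)
  set.seed(42)
  for (case in 1:100) {
    n <- sample(2:20, 1)
    pos <- matrix(runif(n * 3, 0, 3), n, 3)
    vel <- matrix(rnorm(n * 3), n, 3)
    Fv <- interaction_forces(pos, vel, p)
    for (i in sample(n, min(n, 4))) {
      fo <- brute_force_interaction(i, pos, vel, p)
      expect_lt(max(abs(Fv[i, ] - fo)), 1e-10)
      expect_lt(max(abs(interaction_force(i, pos, vel, p) - fo)), 1e-10)
    }
  }
})

test_that("coincident positions and identical velocities never yield NaN", {
  p <- swarm_params(chi_rep = 1, r_rep = 1, chi_ali = 1, r_ali = 2,
                    chi_att = 1, r_att = 3)
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(1.5, 0, 0))
  vel <- matrix(1, 3, 3)        # identical velocities in the alignment zone
  set.seed(1)
  f <- interaction_forces(pos, vel, p)
  expect_true(all(is.finite(f)))
  # coincident pair: repulsion magnitude preserved along a random direction
  expect_equal(sqrt(sum(interaction_force(1, pos[1:2, ], vel[1:2, ], p)^2)),
               p$chi_rep, tolerance = 1e-9)
})

test_that("friction is quadratic drag by default and always dissipative", {
  expect_equal(friction_force(c(0, 0, 0), 3), c(0, 0, 0))
  v <- c(1, 0, 0)
  expect_equal(friction_force(v, 2), -2 * v)            # |v| = 1
  expect_equal(friction_force(c(2, 0, 0), 1), c(-4, 0, 0))
  expect_equal(friction_force(c(2, 0, 0), 1, form = "linear"), c(-2, 0, 0))
  set.seed(7)
  for (k in 1:200) {
    v <- rnorm(3) * 10^runif(1, -3, 2)
    gam <- runif(1, 0, 20)
    expect_lte(sum(friction_force(v, gam) * v), 0)
    expect_lte(sum(friction_force(v, gam, "linear") * v), 0)
  }
  expect_error(friction_force(v, -1), ">= 0")
})

test_that("stimulus response is gated by visual range and directed correctly", {
  p <- swarm_params(chi_res = 5, r_res = 4,
                    chi_rep = 0, r_rep = 0, chi_ali = 0, r_ali = 0,
                    chi_att = 0, r_att = 0)
  tgt <- stimulus(c(0, 10, 0), "target")
  # beyond visual range: Heaviside gate gives zero
  expect_equal(response_force(c(0, 2, 0), tgt, p), c(0, 0, 0))
  # pursuit from directly below: unit force straight up, magnitude chi_res
  expect_equal(response_force(c(0, 7, 0), tgt, p), c(0, 5, 0))
  expect_error(response_force(c(0, 10, 0), tgt, p), "coincident")
})

test_that("escape forces always point 90-180 degrees away from the threat", {
  p <- swarm_params(chi_res = 2, r_res = 10,
                    chi_rep = 0, r_rep = 0, chi_ali = 0, r_ali = 0,
                    chi_att = 0, r_att = 0)
  pred <- stimulus(c(1, 2, 3), "predator")
  r_i <- c(4, 1, -1)
  to_threat <- (pred$position - r_i) / sqrt(sum((pred$position - r_i)^2))
  set.seed(11)
  angles <- replicate(2000, {
    f <- response_force(r_i, pred, p)
    expect_equal(sqrt(sum(f^2)), p$chi_res, tolerance = 1e-9)
    acos(sum(f * to_threat) / sqrt(sum(f^2))) * 180 / pi
  })
  expect_true(all(angles >= 90 - 1e-6))
  expect_true(all(angles <= 180 + 1e-6))
})

test_that("isolated two-body dynamics: repulsion separates, attraction pulls together", {
  # repulsion: start inside r_rep at rest, distance non-decreasing
  p <- swarm_params(chi_rep = 5, r_rep = 1, chi_ali = 0, r_ali = 1,
                    chi_att = 0, r_att = 3)
  cfg <- sim_config(n_insects = 2, n_frames = 30, box = 10, params = p,
                    noise = noise_spec("curl", gain = 0),
                    init_positions = rbind(c(4.8, 5, 5), c(5.2, 5, 5)),
                    seed = 1)
  tr <- simulate_swarm(cfg)
  seps <- sapply(1:30, function(t) sqrt(sum((tr$positions[t, 1, ] - tr$positions[t, 2, ])^2)))
  expect_true(all(diff(seps) >= -1e-9))
  expect_gt(seps[30], seps[1])

  # attraction: separation in (r_ali, r_att), zero velocity -> forces point
  # toward each other
  pa <- swarm_params(chi_rep = 0, r_rep = 0.2, chi_ali = 0, r_ali = 0.5,
                     chi_att = 3, r_att = 4)
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))
  vel <- matrix(0, 2, 3)
  f <- interaction_forces(pos, vel, pa)
  expect_gt(f[1, 1], 0)
  expect_lt(f[2, 1], 0)
})

test_that("parameter validation enforces the zone ordering and config IO round-trips", {
  expect_error(swarm_params(r_rep = 2, r_ali = 1, r_att = 3), "r_att >= r_ali")
  expect_error(swarm_params(scale = 0), "scale")
  expect_error(swarm_params(chi_rep = -1), ">= 0")
  # radius-difference convention
  p <- swarm_params(r_rep = 0.2, r_ali = 10, r_att = 9.2, radii = "diff")
  expect_equal(p$r_ali, 10.2)
  expect_equal(p$r_att, 19.4)
  # config file round trip with exact key names
  p2 <- swarm_params(gamma = 1.4, scale = 0.72, gain = 0.1, chi_rep = 5,
                     r_rep = 0.2, chi_ali = 3, r_ali = 10.2, chi_att = 7,
                     r_att = 19.4, chi_res = 20, r_res = 8)
  path <- tempfile(fileext = ".yaml")
  write_params(p2, path, noise = noise_spec("curl", seed = 3))
  keys <- names(yaml::read_yaml(path))
  expect_true(all(c("gamma", "scale", "gain", "chi_rep", "r_rep", "chi_ali",
                    "r_ali", "chi_att", "r_att", "chi_res", "r_res",
                    "noise.kind") %in% keys))
  back <- read_params(path)
  expect_equal(unclass(back$params), unclass(p2))
  expect_equal(back$noise$kind, "curl")
})
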