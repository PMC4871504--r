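#' Genetic-algorithm settings for parameter estimation
#'
#' @param population number of individuals (>= 4).
#' @param generations number of generations; 0 evaluates only the random
#'   initial population.
#' @param crossover_rate probability that a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate per-gene probability of Gaussian mutation
#'   (sd = 10% of the gene's range, clipped to bounds).
#' @param tournament tournament size for selection.
#' @param elite number of elite individuals copied unchanged (>= 1 keeps the
#'   best-so-far fitness non-decreasing).
#' @param bounds named list of `c(lo, hi)` per estimated parameter; defaults
#'   to `[0, 4x]` the base value (`[0, 1]` when the base is 0).
#' @param estimated_keys which model parameters the GA searches; defaults to
#'   the seven that are identifiable from trajectory data alone (alignment
#'   and stimulus-response parameters are not, absent stimuli and with the
#'   weak alignment real swarms show).
#' @param fitness_frames length of each candidate simulation.
#' @param sim_seed fixed simulation seed used for every fitness evaluation
#'   (reduces fitness noise between candidates).
#' @param seed GA random seed.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population = 30L, generations = 40L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      tournament = 3L, elite = 1L, bounds = NULL,
                      estimated_keys = c("gamma", "chi_rep", "r_rep",
                                         "chi_att", "r_att", "scale", "gain"),
                      fitness_frames = 300L, sim_seed = 1L, seed = 1L) {
  stopifnot(population >= 4, generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament >= 1, elite >= 0)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament = as.integer(tournament),
                 elite = as.integer(elite), bounds = bounds,
                 estimated_keys = estimated_keys,
                 fitness_frames = as.integer(fitness_frames),
                 sim_seed = as.integer(sim_seed), seed = as.integer(seed)),
            class = "ga_config")
}

ga_default_bounds <- function(base_params, keys) {
  bounds <- list()
  for (k in keys) {
    b <- base_params[[k]]
    hi <- if (b > 0) 4 * b else 1
    lo <- if (k == "scale") 1e-3 else 0    # scale must stay positive
    bounds[[k]] <- c(lo, hi)
  }
  bounds
}

# decode a gene vector into a valid swarm_params, repairing the zone radius
# ordering against the fixed (non-estimated) radii
decode_params <- function(genes, base_params, keys) {
  p <- unclass(base_params)
  for (j in seq_along(keys)) p[[keys[j]]] <- genes[j]
  if ("r_rep" %in% keys) p$r_rep <- min(p$r_rep, p$r_ali)
  if ("r_att" %in% keys) p$r_att <- max(p$r_att, p$r_ali)
  class(p) <- "swarm_params"
  p
}

ga_fitness <- function(genes, ref_samples, ref_n, base_config, ga,
                       weights, p1, p2) {
  params <- decode_params(genes, base_config$params, ga$estimated_keys)
  cfg <- base_config
  cfg$params <- params
  cfg$n_frames <- ga$fitness_frames
  cfg$n_insects <- ref_n
  cfg$seed <- ga$sim_seed
  sim <- simulate_swarm(cfg)
  ev <- evaluate_swarm(ref_samples, sim, weights = weights, p1 = p1, p2 = p2)
  list(score = ev$score, energies = ev$raw_energies)
}

#' Estimate dynamics-model parameters from a reference trajectory
#'
#' The parameter-estimation loop: a genetic algorithm searches the estimated
#' parameter subspace, and each candidate is scored by simulating the swarm
#' under the candidate parameters (fixed simulation seed and run length) and
#' computing the weighted distributional similarity between the simulated
#' and the reference trajectories.  Parameters outside `ga$estimated_keys`
#' are held at their `base_config` values.
#'
#' @param reference a [swarm_trajectory()] long enough for all seven metrics
#'   (>= 4 frames).
#' @param base_config a [sim_config()] providing the fixed scenario and the
#'   non-estimated parameter values.
#' @param ga a [ga_config()].
#' @param weights,p1,p2 optional named evaluation weights and normalizers
#'   per metric (defaults: equal weights, `p1 = 0`, `p2 = 1`).
#' @return An object of class `"swarm_fit"`: the best parameter set, its
#'   score and raw energies, the per-generation best-fitness trace, and the
#'   configuration used.
#' @export
par_est <- function(reference, base_config, ga = ga_config(),
                    weights = NULL, p1 = NULL, p2 = NULL) {
  stopifnot(inherits(reference, "swarm_trajectory"),
            inherits(base_config, "sim_config"))
  if (n_frames(reference) < 4)
    stop("reference trajectory too short for the seven metrics (need >= 4 frames)")
  keys <- ga$estimated_keys
  bounds <- ga$bounds %||% ga_default_bounds(base_config$params, keys)
  if (!setequal(names(bounds), keys)) stop("bounds must cover estimated_keys")
  lo <- vapply(bounds[keys], `[`, numeric(1), 1)
  hi <- vapply(bounds[keys], `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("bounds must satisfy lo < hi")
  d <- length(keys)
  ref_samples <- trajectory_metric_samples(reference)
  ref_n <- n_insects(reference)

  with_seed(ga$seed, {
    # initial population: the base parameter values, then uniform draws
    pop <- matrix(stats::runif(ga$population * d, lo, hi),
                  ga$population, d, byrow = TRUE)
    base_genes <- pmin(pmax(vapply(keys, function(k) base_config$params[[k]],
                                   numeric(1)), lo), hi)
    pop[1, ] <- base_genes

    evaluate_pop <- function(pop) {
      lapply(seq_len(nrow(pop)), function(i)
        ga_fitness(pop[i, ], ref_samples, ref_n, base_config, ga,
                   weights, p1, p2))
    }
    evals <- evaluate_pop(pop)
    fit <- vapply(evals, `[[`, numeric(1), "score")
    best_i <- which.max(fit)
    best <- list(genes = pop[best_i, ], score = fit[best_i],
                 energies = evals[[best_i]]$energies)
    trace <- best$score

    if (ga$generations > 0) {
      for (gen in seq_len(ga$generations)) {
        newpop <- matrix(0, ga$population, d)
        # elitism
        ord <- order(fit, decreasing = TRUE)
        n_elite <- min(ga$elite, ga$population)
        if (n_elite > 0) newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
        # tournament selection + uniform crossover + Gaussian mutation
        i <- n_elite
        while (i < ga$population) {
          pa <- pop[tournament_pick(fit, ga$tournament), ]
          pb <- pop[tournament_pick(fit, ga$tournament), ]
          if (stats::runif(1) < ga$crossover_rate) {
            mask <- stats::runif(d) < 0.5
            tmp <- pa
            pa[mask] <- pb[mask]
            pb[mask] <- tmp[mask]
          }
          for (child in list(pa, pb)) {
            if (i >= ga$population) break
            i <- i + 1
            mut <- stats::runif(d) < ga$mutation_rate
            child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1 * (hi - lo)[mut])
            newpop[i, ] <- pmin(pmax(child, lo), hi)
          }
        }
        pop <- newpop
        evals <- evaluate_pop(pop)
        fit <- vapply(evals, `[[`, numeric(1), "score")
        gi <- which.max(fit)
        if (fit[gi] > best$score)
          best <- list(genes = pop[gi, ], score = fit[gi],
                       energies = evals[[gi]]$energies)
        trace <- c(trace, best$score)
      }
    }

    params <- decode_params(best$genes, base_config$params, keys)
    structure(list(params = params, score = best$score,
                   energies = best$energies, trace = trace,
                   estimated_keys = keys, bounds = bounds,
                   ga = ga, base_config = base_config,
                   reference_dim = dim(reference$positions)),
              class = "swarm_fit")
  })
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.max(fit[cand])]
}

#' @export
print.swarm_fit <- function(x, ...) {
  cat("Swarm dynamics model fit (genetic-algorithm parameter estimate)\n")
  cat(sprintf("  evaluation score: %.4f after %d generation(s)\n",
              x$score, length(x$trace) - 1))
  cat("  estimated parameters:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.swarm_fit <- function(object, ...) {
  cat("Swarm dynamics model fit\n")
  cat(sprintf("  reference: %d frames x %d insects\n",
              object$reference_dim[1], object$reference_dim[2]))
  cat(sprintf("  GA: population %d, %d generations, seed %d\n",
              object$ga$population, object$ga$generations, object$ga$seed))
  cat(sprintf("  best evaluation score: %.4f\n", object$score))
  cat("  raw energies (L1 distances):\n")
  print(round(object$energies, 4))
  cat("  estimated parameters (with search bounds):\n")
  b <- do.call(rbind, object$bounds[object$estimated_keys])
  tab <- cbind(estimate = coef(object), lo = b[, 1], hi = b[, 2])
  print(round(tab, 4))
  invisible(object)
}

#' @export
coef.swarm_fit <- function(object, ...) {
  vapply(object$estimated_keys, function(k) object$params[[k]], numeric(1))
}

#' @export
plot.swarm_fit <- function(x, y, ...) {
  graphics::plot(seq_along(x$trace) - 1, x$trace, type = "b",
                 xlab = "generation", ylab = "best evaluation score",
                 main = "GA fitness trace", ...)
  invisible(x)
}

#' Simulate from a fitted swarm model
#'
#' Runs the base scenario under the fitted parameters.
#'
#' @param object a `"swarm_fit"` from [par_est()].
#' @param nsim number of trajectories.
#' @param seed base seed; run `k` uses `seed + k - 1`.
#' @param n_frames run length (default: the fitness run length).
#' @param ... unused.
#' @return a list of [swarm_trajectory()] (a single trajectory if
#'   `nsim = 1`).
#' @export
simulate.swarm_fit <- function(object, nsim = 1, seed = 1L,
                               n_frames = NULL, ...) {
  cfg <- object$base_config
  cfg$params <- object$params
  cfg$n_frames <- as.integer(n_frames %||% object$ga$fitness_frames)
  out <- lapply(seq_len(nsim), function(k) {
    cfg$seed <- as.integer(seed + k - 1)
    simulate_swarm(cfg)
  })
  if (nsim == 1) out[[1]] else out
}

#' Iterative entropy-weighted comparison of simulation models
#'
#' Scores `m >= 2` candidate simulation models against one reference
#' trajectory.  Each iteration (1) re-estimates every model's parameters by
#' [par_est()] under the current weights, collecting the raw energy matrix,
#' (2) recomputes entropy weights and min-max normalizers from that matrix,
#' and (3) stops when the weights move less than `tol` (max absolute
#' change) or after `max_iter` iterations.  Final scores use the last
#' weights and normalizers; columns with zero spread get weight 0 and do
#' not contribute.
#'
#' @param models named list, one entry per candidate model: either a
#'   [sim_config()] or a list `list(config = , ga = )` when a model needs
#'   its own GA settings (e.g. a different estimated parameter subset for
#'   an ablated model class).
#' @param reference a [swarm_trajectory()].
#' @param ga default [ga_config()] for models without their own.
#' @param max_iter maximum weight iterations.
#' @param tol convergence tolerance on the weights.
#' @return object of class `"swarm_comparison"`: per-model scores, fits,
#'   the final weights/normalizers, the energy matrix and iteration count.
#' @export
compare_models <- function(models, reference, ga = ga_config(),
                           max_iter = 10L, tol = 1e-3) {
  stopifnot(length(models) >= 2)
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  models <- lapply(models, function(m) {
    if (inherits(m, "sim_config")) list(config = m, ga = ga) else m
  })
  ids <- swarm_metric_ids()
  weights <- stats::setNames(rep(1 / 7, 7), ids)
  p1 <- stats::setNames(rep(0, 7), ids)
  p2 <- stats::setNames(rep(1, 7), ids)
  fits <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fits <- lapply(models, function(m)
      par_est(reference, m$config, m$ga, weights = weights, p1 = p1, p2 = p2))
    X <- do.call(rbind, lapply(fits, `[[`, "energies"))
    colnames(X) <- ids
    ew <- entropy_weights(X)
    delta <- max(abs(ew$weights - weights))
    weights <- ew$weights
    p1 <- ew$p1
    p2 <- ew$p2
    if (iter >= max_iter || delta < tol) break
  }
  # final scores under the converged weights; degenerate columns (p2 = 0)
  # carry weight 0 and are excluded from the normalized sum
  scores <- apply(do.call(rbind, lapply(fits, `[[`, "energies")), 1, function(en) {
    norm <- ifelse(p2 > 0, (en - p1) / p2, 0)
    1 - sum(weights * norm)
  })
  structure(list(scores = stats::setNames(scores, names(models)),
                 fits = fits, weights = weights, p1 = p1, p2 = p2,
                 energy_matrix = do.call(rbind, lapply(fits, `[[`, "energies")),
                 iterations = iter),
            class = "swarm_comparison")
}

#' @export
print.swarm_comparison <- function(x, ...) {
  cat("Entropy-weighted model comparison\n")
  cat(sprintf("  %d iteration(s); final weights:\n", x$iterations))
  print(round(x$weights, 4))
  cat("  scores (higher = closer to the reference):\n")
  print(round(sort(x$scores, decreasing = TRUE), 4))
  invisible(x)
}

#' Synthetic trajectory fixtures
#'
#' Stand-ins for motion-capture swarm recordings, used for testing and
#' calibration experiments.  `"swarmlike"` runs the full dynamics + curl
#' noise model with documented defaults emulating a laboratory midge swarm:
#' noisy, box-bounded, weakly aligned kinematics.  The other kinds are
#' analytic trajectories with closed-form metric values: `"lattice"` (a
#' static cubic grid), `"straightline"` (constant velocities, so all
#' angular metrics and the jerk are exactly zero), and `"two_body"` (two
#' insects travelling with a common velocity at fixed separation).
#'
#' @param kind fixture type.
#' @param n_insects,n_frames,dt trajectory dimensions.
#' @param seed integer seed (`swarmlike` is fully reproducible from it).
#' @param separation two-body separation (world units).
#' @return a [swarm_trajectory()].
#' @export
generate_fixture <- function(kind = c("swarmlike", "lattice", "straightline",
                                      "two_body"),
                             n_insects = 50L, n_frames = 300L, dt = 1 / 60,
                             seed = 1L, separation = 2) {
  kind <- match.arg(kind)
  if (kind == "swarmlike") {
    cfg <- swarmlike_config(n_insects, n_frames, dt, seed)
    traj <- simulate_swarm(cfg)
    traj$metadata$fixture <- "swarmlike"
    return(traj)
  }
  p <- array(0, c(n_frames, n_insects, 3))
  if (kind == "lattice") {
    side <- ceiling(n_insects^(1 / 3))
    g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    g <- as.matrix(g[seq_len(n_insects), ])
    for (t in seq_len(n_frames)) p[t, , ] <- g
  } else if (kind == "straightline") {
    vel <- with_seed(seed, matrix(stats::runif(n_insects * 3, -2, 2),
                                  n_insects, 3))
    start <- with_seed(seed + 1, matrix(stats::runif(n_insects * 3, 0, 10),
                                        n_insects, 3))
    for (t in seq_len(n_frames))
      p[t, , ] <- start + (t - 1) * dt * vel
  } else {                       # two_body
    if (n_insects != 2) n_insects <- 2L
    p <- array(0, c(n_frames, 2, 3))
    v <- c(1, 0.5, 0)
    for (t in seq_len(n_frames)) {
      base <- (t - 1) * dt * v
      p[t, 1, ] <- base
      p[t, 2, ] <- base + c(0, 0, separation)
    }
  }
  swarm_trajectory(p, dt, metadata = list(fixture = kind, seed = seed))
}

# The swarmlike fixture's generating model: a 10-unit box, moderate
# repulsion/attraction, no alignment (midge-like), curl noise.  These
# defaults define the synthetic study conditions used by the recovery and
# ablation experiments.
swarmlike_config <- function(n_insects = 50L, n_frames = 300L, dt = 1 / 60,
                             seed = 1L) {
  sim_config(
    n_insects = n_insects, dt = dt, n_frames = n_frames,
    box = 10, boundary_mode = "reflect",
    params = swarm_params(gamma = 2, scale = 1, gain = 2,
                          chi_rep = 2, r_rep = 0.3,
                          chi_ali = 0, r_ali = 0.3,
                          chi_att = 6, r_att = 4),
    noise = noise_spec("curl", seed = seed),
    avoidance = avoidance_config(agent_radius = 0.05, time_horizon = 0.25,
                                 max_speed = 8, dt = dt),
    seed = seed)
}
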