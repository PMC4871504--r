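#' Simulation configuration
#'
#' Everything needed to run one swarm simulation: swarm size, time stepping,
#' the world box, the dynamics parameters, the noise field, the
#' collision-avoidance settings, environmental stimuli, and the seed.
#'
#' The noise field's `scale` and `gain` always track the corresponding
#' dynamics parameters (they are two of the 11 model parameters); the spec
#' object contributes the noise `kind`, Gaussian strength `lambda` and the
#' lattice seed.
#'
#' @param n_insects number of insects (>= 1).
#' @param dt time step (> 0); default 1/60 s, a motion-capture-like frame
#'   rate.
#' @param n_frames number of frames in the produced trajectory (the first
#'   frame is the initial state).
#' @param box world bounds: a 2 x 3 matrix `rbind(lower, upper)` or a single
#'   number `L` meaning the cube `[0, L]^3`.
#' @param boundary_mode `"reflect"` (enclosed box) or `"none"` (open field).
#' @param params a [swarm_params()].
#' @param noise a [noise_spec()]; its `scale`/`gain` are overridden by
#'   `params$scale`/`params$gain` at run time.
#' @param avoidance an [avoidance_config()]; its `dt` is synced to `dt`.
#' @param stimuli list of [stimulus()] objects (at most one is acted on per
#'   step: the first active one).
#' @param obstacles list of [sphere_obstacle()]s.
#' @param schedule optional named list of length-2 numeric vectors
#'   `c(start, end)`: the named parameters are ramped linearly across the
#'   run (used e.g. for the phase-transition scenario).
#' @param drag_form `"quadratic"` or `"linear"` friction (see
#'   [friction_force()]).
#' @param seed integer seed; together with the config it fully determines
#'   the trajectory.
#' @param init_positions,init_velocities optional `n x 3` matrices fixing
#'   the initial state instead of the default uniform-position /
#'   zero-velocity initialization.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_insects = 100L, dt = 1 / 60, n_frames = 500L,
                       box = 20, boundary_mode = c("reflect", "none"),
                       params = swarm_params(), noise = noise_spec("curl"),
                       avoidance = avoidance_config(dt = dt),
                       stimuli = list(), obstacles = list(),
                       schedule = NULL,
                       drag_form = c("quadratic", "linear"),
                       seed = 1L, init_positions = NULL,
                       init_velocities = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  drag_form <- match.arg(drag_form)
  if (length(box) == 1) box <- rbind(c(0, 0, 0), rep(as.numeric(box), 3))
  box <- matrix(as.numeric(box), 2, 3)
  stopifnot(n_insects >= 1, dt > 0, n_frames >= 1, all(box[2, ] > box[1, ]))
  validate_swarm_params(params)
  avoidance$dt <- dt
  if (!is.null(schedule)) {
    stopifnot(is.list(schedule), !is.null(names(schedule)),
              all(lengths(schedule) == 2))
  }
  structure(list(n_insects = as.integer(n_insects), dt = dt,
                 n_frames = as.integer(n_frames), box = box,
                 boundary_mode = boundary_mode, params = params,
                 noise = noise, avoidance = avoidance, stimuli = stimuli,
                 obstacles = obstacles, schedule = schedule,
                 drag_form = drag_form, seed = as.integer(seed),
                 init_positions = init_positions,
                 init_velocities = init_velocities),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Swarm simulation config: %d insects, %d frames, dt = %g\n",
              x$n_insects, x$n_frames, x$dt))
  cat(sprintf("  box: [%g, %g] x [%g, %g] x [%g, %g] (%s)\n",
              x$box[1, 1], x$box[2, 1], x$box[1, 2], x$box[2, 2],
              x$box[1, 3], x$box[2, 3], x$boundary_mode))
  cat("  noise:", x$noise$kind, " seed:", x$seed, "\n")
  invisible(x)
}

# Effective parameters at a given frame under the linear ramp schedule.
scheduled_params <- function(cfg, frame) {
  p <- cfg$params
  if (is.null(cfg$schedule)) return(p)
  frac <- if (cfg$n_frames > 1) (frame - 1) / (cfg$n_frames - 1) else 0
  for (key in names(cfg$schedule)) {
    se <- cfg$schedule[[key]]
    p[[key]] <- se[1] + frac * (se[2] - se[1])
  }
  p
}

effective_noise <- function(spec, params) {
  spec$scale <- params$scale
  spec$gain <- params$gain
  spec
}

check_finite_forces <- function(...) {
  forces <- list(...)
  for (nm in names(forces)) {
    if (any(!is.finite(forces[[nm]])))
      stop("non-finite force in term '", nm, "'")
  }
}

#' Advance the swarm by one time step
#'
#' One explicit Euler step of the dynamics: classify neighbours, accumulate
#' the interaction force, friction, stimulus response and noise force for
#' each insect, form the preferred velocity
#' `v_pref = v + (F_int + F_pro) * dt`, pass all preferred velocities
#' through the collision-avoidance operator, and move each insect by the
#' returned velocity.  Reflecting boundaries are applied last.
#'
#' @param positions,velocities `n x 3` matrices of the current state.
#' @param cfg a [sim_config()].
#' @param frame frame index being produced (used by stimuli and schedules).
#' @return list with updated `positions` and `velocities`.
#' @export
step_swarm <- function(positions, velocities, cfg, frame = 2L) {
  params <- scheduled_params(cfg, frame)
  time <- (frame - 1) * cfg$dt
  n <- nrow(positions)

  f_int <- interaction_forces(positions, velocities, params)
  f_fric <- friction_force(velocities, params$gamma, cfg$drag_form)
  f_res <- matrix(0, n, 3)
  stim <- NULL
  for (s in cfg$stimuli) if (stimulus_active(s, frame)) { stim <- s; break }
  if (!is.null(stim) && params$chi_res > 0) {
    for (i in seq_len(n))
      f_res[i, ] <- response_force(positions[i, ], stim, params, frame, time)
  }
  f_noise <- noise_forces(positions, effective_noise(cfg$noise, params))
  check_finite_forces(interaction = f_int, friction = f_fric,
                      response = f_res, noise = f_noise)

  preferred <- velocities + (f_int + f_fric + f_res + f_noise) * cfg$dt
  v_new <- resolve_velocities(positions, velocities, preferred,
                              cfg$avoidance, cfg$obstacles)
  p_new <- positions + v_new * cfg$dt

  if (cfg$boundary_mode == "reflect") {
    for (k in 1:3) {
      lo <- cfg$box[1, k]; hi <- cfg$box[2, k]
      below <- p_new[, k] < lo
      above <- p_new[, k] > hi
      p_new[below, k] <- 2 * lo - p_new[below, k]
      p_new[above, k] <- 2 * hi - p_new[above, k]
      v_new[below | above, k] <- -v_new[below | above, k]
      # clamp any overshoot past the opposite wall
      p_new[, k] <- pmin(pmax(p_new[, k], lo), hi)
    }
  }
  list(positions = p_new, velocities = v_new)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Run a swarm simulation
#'
#' Initializes insect positions uniformly in the box with zero velocities
#' (from the seeded stream) and advances the dynamics for
#' `cfg$n_frames - 1` steps.  The result is fully determined by
#' `(cfg, cfg$seed)`; the caller's RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return a [swarm_trajectory()]; `metadata$per_frame` logs per-frame swarm
#'   density (insects per box volume) and mean speed.
#' @export
simulate_swarm <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_insects
    F <- cfg$n_frames
    if (is.null(cfg$init_positions)) {
      pos <- sapply(1:3, function(k) stats::runif(n, cfg$box[1, k], cfg$box[2, k]))
      pos <- matrix(pos, n, 3)
    } else {
      pos <- as_position_matrix(cfg$init_positions)
      stopifnot(nrow(pos) == n)
    }
    vel <- if (is.null(cfg$init_velocities)) matrix(0, n, 3)
           else as_position_matrix(cfg$init_velocities)
    traj <- array(NA_real_, c(F, n, 3))
    traj[1, , ] <- pos
    mean_speed <- numeric(F)
    if (F > 1) {
      for (f in 2:F) {
        st <- step_swarm(pos, vel, cfg, frame = f)
        pos <- st$positions
        vel <- st$velocities
        traj[f, , ] <- pos
        mean_speed[f] <- mean(sqrt(rowSums(vel^2)))
      }
    }
    vol <- prod(cfg$box[2, ] - cfg$box[1, ])
    swarm_trajectory(traj, cfg$dt, metadata = list(
      scenario = cfg$scenario %||% NULL,
      seed = cfg$seed,
      params = cfg$params,
      per_frame = data.frame(frame = seq_len(F),
                             density = n / vol,
                             mean_speed = mean_speed)))
  })
}

#' Reference density of flying insects at a given temperature
#'
#' Airborne insect density varies with weather; over temperature it follows
#' a second-order polynomial, `N(T) = -0.1073 T^2 + 4.7643 T - 33.4556`
#' insects per unit volume, peaking near 22 degrees C.  The value is a
#' reference annotation only: the simulator does not closed-loop control its
#' own density to match it.
#'
#' @param T_celsius temperature in degrees Celsius (vectorised).
#' @return density (insects per unit volume); negative polynomial values are
#'   clamped to zero with a warning.
#' @export
temperature_to_density <- function(T_celsius) {
  N <- -0.1073 * T_celsius^2 + 4.7643 * T_celsius - 33.4556
  if (any(N < 0)) {
    warning("polynomial density negative at some temperatures; clamped to 0")
    N[N < 0] <- 0
  }
  N
}

#' Swarm density against a fixed reference volume
#'
#' Insect count divided by a fixed reference volume, the convention under
#' which density is proportional to swarm size when the space is held fixed.
#'
#' @param traj a [swarm_trajectory()] (only the insect count is used).
#' @param reference_volume volume (> 0).
#' @return per-frame density vector (constant: count/volume each frame).
#' @export
measure_density <- function(traj, reference_volume) {
  if (reference_volume <= 0) stop("reference_volume must be > 0")
  rep(n_insects(traj) / reference_volume, n_frames(traj))
}
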