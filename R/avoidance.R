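#' Collision-avoidance configuration
#'
#' Settings of the reciprocal velocity-obstacle operator that maps preferred
#' velocities to collision-free actual velocities.
#'
#' @param agent_radius collision radius of one insect (world length units).
#'   Default 0.05, half a midge-like body length on the world scale used by
#'   the box scenarios.
#' @param time_horizon how far into the future pairwise collisions are
#'   forbidden (time units); must be >= `dt`.
#' @param max_speed hard cap on returned speeds.
#' @param dt simulation time step.
#' @param infeasible_policy what to do for an agent whose linear program is
#'   infeasible (very dense neighbourhoods): `"zero_velocity"` stops the
#'   insect for that frame; `"halve_step"` retries the computation with a
#'   halved time step (up to 4 times) before stopping it.
#' @return An object of class `"avoidance_config"`.
#' @export
avoidance_config <- function(agent_radius = 0.05, time_horizon = 0.5,
                             max_speed = 10, dt = 1 / 60,
                             infeasible_policy = c("zero_velocity", "halve_step")) {
  infeasible_policy <- match.arg(infeasible_policy)
  stopifnot(agent_radius > 0, time_horizon > 0, max_speed > 0, dt > 0)
  if (time_horizon < dt) stop("time_horizon must be >= dt")
  structure(list(agent_radius = agent_radius, time_horizon = time_horizon,
                 max_speed = max_speed, dt = dt,
                 infeasible_policy = infeasible_policy),
            class = "avoidance_config")
}

#' Spherical static obstacle
#'
#' @param position centre, 3-vector.
#' @param radius sphere radius (> 0).
#' @return a list usable in the `obstacles` argument of
#'   [resolve_velocities()] and [sim_config()].
#' @export
sphere_obstacle <- function(position, radius) {
  stopifnot(length(position) == 3, radius > 0)
  list(position = as.numeric(position), radius = as.numeric(radius))
}

#' Map preferred velocities to reciprocally collision-free velocities
#'
#' The avoidance operator: each neighbour induces a half-space constraint in
#' velocity space (derived from the truncated velocity-obstacle cone, with
#' the avoidance effort shared reciprocally between the pair), and each
#' agent receives the feasible velocity closest in 2-norm to its preferred
#' velocity, capped at `max_speed`.  Agents whose constraint set is
#' infeasible are handled per `cfg$infeasible_policy`.
#'
#' @param positions,velocities `n x 3` matrices of current states.
#' @param preferred `n x 3` matrix of preferred velocities.
#' @param cfg an [avoidance_config()].
#' @param obstacles optional list of [sphere_obstacle()]s.
#' @return an `n x 3` matrix of collision-free velocities, with attribute
#'   `"infeasible"` (logical vector) flagging agents that hit the policy.
#' @export
resolve_velocities <- function(positions, velocities, preferred, cfg,
                               obstacles = NULL) {
  positions <- as_position_matrix(positions)
  velocities <- as_position_matrix(velocities)
  preferred <- as_position_matrix(preferred)
  n <- nrow(positions)
  stopifnot(nrow(velocities) == n, nrow(preferred) == n)
  if (length(obstacles)) {
    op <- do.call(rbind, lapply(obstacles, `[[`, "position"))
    orad <- vapply(obstacles, `[[`, numeric(1), "radius")
  } else {
    op <- matrix(0, 0, 3)
    orad <- numeric(0)
  }
  res <- .orca_resolve(positions, velocities, preferred,
                       cfg$agent_radius, cfg$time_horizon, cfg$dt,
                       cfg$max_speed,
                       if (cfg$infeasible_policy == "halve_step") 1L else 0L,
                       op, orad)
  out <- res$velocities
  attr(out, "infeasible") <- as.logical(res$infeasible)
  out
}
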