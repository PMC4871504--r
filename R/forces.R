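#' Zone indicator for the concentric interaction zones
#'
#' The piecewise function distinguishing the repulsion, alignment and
#' attraction zones around an insect: it is -1 on `[0, r_rep)`, 0 on
#' `[r_rep, r_ali)` and +1 on `[r_ali, r_att]`.  Distances beyond `r_att`
#' belong to no zone (neighbours are pre-filtered) and raise an error.
#'
#' @param x non-negative distance (scalar or vector).
#' @param params a [swarm_params()] object.
#' @return integer vector in `{-1, 0, 1}`, same length as `x`.
#' @export
zone_indicator <- function(x, params) {
  validate_swarm_params(params)
  x <- as.numeric(x)
  if (any(x < 0)) stop("distance must be >= 0")
  if (any(x > params$r_att))
    stop("zone_indicator called with distance beyond r_att; ",
         "neighbours must be pre-filtered")
  g <- integer(length(x))
  g[x < params$r_rep] <- -1L
  g[x >= params$r_ali] <- 1L
  g
}

#' Neighbours of one insect
#'
#' All other insects within distance `r_att` of insect `i`.
#'
#' @param positions numeric matrix, one row per insect, 3 columns.
#' @param i index of the focal insect.
#' @param r_att neighbourhood radius (>= 0).
#' @return integer vector of neighbour row indices (never contains `i`).
#' @export
neighbor_indices <- function(positions, i, r_att) {
  positions <- as_position_matrix(positions)
  n <- nrow(positions)
  if (i < 1 || i > n) stop("agent index out of range")
  if (r_att < 0) stop("r_att must be >= 0")
  d <- sqrt(colSums((t(positions) - positions[i, ])^2))
  which(d <= r_att & seq_len(n) != i)
}

as_position_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.null(dim(x)) && length(x) == 3) x <- matrix(x, 1, 3)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("positions must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Zonal interaction force on one insect
#'
#' The net social force on insect `i`: for each zone k in
#' {repulsion, alignment, attraction} the influences of the `N_k` neighbours
#' in that zone are averaged,
#' `F_k = (chi_k/N_k) * sum_j [ g(r_ji) rhat_ji + (1-|g(r_ji)|) vhat_ji ]`,
#' and the three zone forces are summed.  `rhat_ji` is the unit vector from
#' `i` to `j` and `vhat_ji` the unit relative velocity; with `g = -1` (+1)
#' the velocity term vanishes and the force points away from (toward)
#' neighbours, while `g = 0` (alignment zone) leaves only the
#' velocity-matching term.  Empty zones contribute nothing.
#'
#' Degenerate geometry is handled deterministically given the RNG state:
#' coincident positions (`r_ji < 1e-9`) replace `rhat_ji` by a random unit
#' vector (symmetry breaking), and near-identical velocities
#' (`|v_j - v_i| < 1e-12`) drop the alignment contribution of that pair.
#'
#' @param i focal insect index.
#' @param positions,velocities numeric matrices, one row per insect.
#' @param params a [swarm_params()] object.
#' @return numeric 3-vector.
#' @export
interaction_force <- function(i, positions, velocities, params) {
  positions <- as_position_matrix(positions)
  velocities <- as_position_matrix(velocities)
  nb <- neighbor_indices(positions, i, params$r_att)
  if (!length(nb)) return(c(0, 0, 0))
  dr <- positions[nb, , drop = FALSE] -
    matrix(positions[i, ], length(nb), 3, byrow = TRUE)
  dv <- velocities[nb, , drop = FALSE] -
    matrix(velocities[i, ], length(nb), 3, byrow = TRUE)
  rji <- sqrt(rowSums(dr^2))
  g <- zone_indicator(rji, params)

  rhat <- dr / ifelse(rji > 1e-9, rji, 1)
  coincident <- which(rji < 1e-9)
  for (k in coincident) rhat[k, ] <- random_unit_vector()
  vnorm <- sqrt(rowSums(dv^2))
  vhat <- dv / ifelse(vnorm > 1e-12, vnorm, 1)
  vhat[vnorm < 1e-12, ] <- 0

  total <- c(0, 0, 0)
  chi <- c(params$chi_rep, params$chi_ali, params$chi_att)
  for (zone in c(-1L, 0L, 1L)) {
    sel <- which(g == zone)
    if (!length(sel)) next
    term <- g[sel] * rhat[sel, , drop = FALSE] +
      (1 - abs(g[sel])) * vhat[sel, , drop = FALSE]
    total <- total + chi[zone + 2L] * colSums(term) / length(sel)
  }
  total
}

#' All interaction forces at once (vectorised over insects)
#'
#' Matrix version of [interaction_force()]; identical numerics, used by the
#' simulation stepper.
#'
#' @inheritParams interaction_force
#' @return numeric matrix, one force row per insect.
#' @export
interaction_forces <- function(positions, velocities, params) {
  positions <- as_position_matrix(positions)
  velocities <- as_position_matrix(velocities)
  n <- nrow(positions)
  out <- matrix(0, n, 3)
  if (n < 2 || params$r_att <= 0 ||
      (params$chi_rep == 0 && params$chi_ali == 0 && params$chi_att == 0))
    return(out)
  d2 <- pairwise_sq_dist(positions)
  diag(d2) <- Inf
  pr <- which(d2 <= params$r_att^2, arr.ind = TRUE)  # ordered pairs (i, j)
  if (!nrow(pr)) return(out)
  i <- pr[, 1]; j <- pr[, 2]

  dr <- positions[j, , drop = FALSE] - positions[i, , drop = FALSE]
  dv <- velocities[j, , drop = FALSE] - velocities[i, , drop = FALSE]
  rji <- sqrt(rowSums(dr^2))
  g <- numeric(length(rji))
  g[rji < params$r_rep] <- -1
  g[rji >= params$r_ali] <- 1

  rhat <- dr / pmax(rji, 1e-9)
  co <- which(rji < 1e-9)
  for (k in co) rhat[k, ] <- random_unit_vector()
  vnorm <- sqrt(rowSums(dv^2))
  vhat <- dv / pmax(vnorm, 1e-12)
  vhat[vnorm < 1e-12, ] <- 0

  term <- g * rhat + (1 - abs(g)) * vhat
  chi <- c(params$chi_rep, params$chi_ali, params$chi_att)
  for (zone in c(-1, 0, 1)) {
    if (chi[zone + 2] == 0) next
    sel <- g == zone
    if (!any(sel)) next
    sums <- rowsum(term[sel, , drop = FALSE], i[sel])
    counts <- tabulate(i[sel], nbins = n)
    rows <- as.integer(rownames(sums))
    out[rows, ] <- out[rows, ] + chi[zone + 2] * sums / counts[rows]
  }
  out
}

pairwise_sq_dist <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Aerodynamic drag on an insect
#'
#' Quadratic drag `-gamma * |v| * v` by default (the drag scales with the
#' scalar speed times the velocity vector); `form = "linear"` gives Stokes
#' drag `-gamma * v`.  Either way the dissipated power `F . v` is never
#' positive.
#'
#' @param v velocity 3-vector (or matrix of row vectors).
#' @param gamma friction coefficient (>= 0).
#' @param form `"quadratic"` (default) or `"linear"`.
#' @return force of the same shape as `v`.
#' @export
friction_force <- function(v, gamma, form = c("quadratic", "linear")) {
  form <- match.arg(form)
  if (gamma < 0) stop("gamma must be >= 0")
  if (is.matrix(v)) {
    if (form == "linear") return(-gamma * v)
    return(-gamma * sqrt(rowSums(v^2)) * v)
  }
  if (form == "linear") return(-gamma * v)
  -gamma * sqrt(sum(v^2)) * v
}

#' Stimulus response force (pursuit or escape)
#'
#' Zero unless the stimulus lies within the visual range `r_res` (a Heaviside
#' gate on distance).  For a pursuit target the insect is pushed straight at
#' the stimulus with magnitude `chi_res`.  For a predator the unit vector
#' pointing away from the threat is rotated about the world y-axis
#' `n = (0, 1, 0)` by a random angle `theta ~ U[-pi/2, 0]`, so that the force
#' direction always lies in the 90-180 degree sector away from the threat.
#'
#' @param r_i insect position (3-vector).
#' @param stim a [stimulus()] object.
#' @param params a [swarm_params()] object (`chi_res`, `r_res`).
#' @param frame,time frame index and simulation time used to place moving
#'   stimuli.
#' @return numeric 3-vector.
#' @export
response_force <- function(r_i, stim, params, frame = 1L, time = 0) {
  if (is.null(stim) || !stimulus_active(stim, frame)) return(c(0, 0, 0))
  r_e <- stimulus_position(stim, frame, time)
  diff <- as.numeric(r_i) - r_e
  dist <- sqrt(sum(diff^2))
  if (dist > params$r_res) return(c(0, 0, 0))
  if (dist < 1e-12)
    stop("insect coincident with stimulus: response direction undefined")
  rhat_ie <- diff / dist       # unit vector from stimulus to insect
  if (stim$s_e == 1L) {        # escape: rotate the away-direction
    theta <- stats::runif(1, -pi / 2, 0)
    params$chi_res * rotate_about_axis(rhat_ie, c(0, 1, 0), theta)
  } else {                     # pursuit: straight toward the stimulus
    -params$chi_res * rhat_ie
  }
}

#' Rotate a vector about an axis (Rodrigues' formula)
#'
#' @param v 3-vector to rotate.
#' @param n rotation axis (normalised internally).
#' @param theta rotation angle, radians.
#' @return rotated 3-vector.
#' @keywords internal
rotate_about_axis <- function(v, n, theta) {
  n <- n / sqrt(sum(n^2))
  v * cos(theta) + cross3(n, v) * sin(theta) + n * sum(n * v) * (1 - cos(theta))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
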