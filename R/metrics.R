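#' The seven time-varying trajectory metrics
#'
#' `swarm_metric_ids()` lists the metric identifiers:
#' \describe{
#'   \item{`v`}{speed, from forward-difference velocities.}
#'   \item{`a`}{acceleration magnitude (second difference).}
#'   \item{`omega`}{angular velocity: the turning angle between consecutive
#'     velocity vectors per unit time, `arccos(v1.v2/(|v1||v2|))/dt`.}
#'   \item{`alpha`}{angular acceleration, `d omega / dt`.}
#'   \item{`mu`}{Cartesian jerk: `|dv1 - dv2| / dt^2` over consecutive
#'     velocity increments — a roughness proxy for noisy flight.}
#'   \item{`d`}{shortest distance: distance to the nearest neighbour, a
#'     density proxy.}
#'   \item{`eta`}{velocity difference: nearest-neighbour speed minus own
#'     speed, divided by `d` — distinguishes weakly aligned swarms from
#'     flocks.}
#' }
#' @return character vector of the seven ids.
#' @export
swarm_metric_ids <- function() c("v", "a", "omega", "alpha", "mu", "d", "eta")

# velocities V[t,i,] = (P[t+1]-P[t])/dt, an (F-1) x N x 3 array
trajectory_velocities <- function(traj) {
  p <- traj$positions
  F <- dim(p)[1]
  (p[-1, , , drop = FALSE] - p[-F, , , drop = FALSE]) / traj$dt
}

# rowwise squared magnitude of a T x N x 3 array, as a T x N matrix
mag2_matrix <- function(A) {
  d <- dim(A)
  matrix(A[, , 1]^2 + A[, , 2]^2 + A[, , 3]^2, d[1], d[2])
}

#' Compute one metric over a whole trajectory
#'
#' Produces one sample per insect per eligible frame (eligibility depends on
#' the finite-difference stencil: 2 frames for `v`, 3 for `a`/`omega`, 4 for
#' `alpha`/`mu`; `d` uses every frame and `eta` every velocity frame).
#' Angular samples where a velocity has zero magnitude are skipped (the
#' direction is undefined) and the arccos argument is clamped to `[-1, 1]`.
#'
#' @param metric one of [swarm_metric_ids()].
#' @param traj a [swarm_trajectory()].
#' @param eta_signed keep the sign of the nearest-neighbour speed difference
#'   (default, as defined); `FALSE` takes its absolute value.
#' @return object of class `"metric_samples"`: list with `metric` and the
#'   numeric `values`.
#' @export
compute_metric <- function(metric, traj, eta_signed = TRUE) {
  metric <- match.arg(metric, swarm_metric_ids())
  p <- traj$positions
  F <- dim(p)[1]; N <- dim(p)[2]; dt <- traj$dt
  need <- c(v = 2, a = 3, omega = 3, alpha = 4, mu = 4, d = 1, eta = 2)[[metric]]
  if (F < need)
    stop(sprintf("metric '%s' needs at least %d frames, trajectory has %d",
                 metric, need, F))
  if (metric %in% c("d", "eta") && N < 2)
    stop("metrics 'd' and 'eta' need at least 2 insects")

  V <- trajectory_velocities(traj)      # (F-1) x N x 3

  values <- switch(metric,
    v = as.numeric(sqrt(mag2_matrix(V))),
    a = {
      A <- (V[-1, , , drop = FALSE] - V[-(F - 1), , , drop = FALSE]) / dt
      as.numeric(sqrt(mag2_matrix(A)))
    },
    omega = as.numeric(angular_velocity_matrix(V, dt)),
    alpha = {
      om <- angular_velocity_matrix(V, dt)  # (F-2) x N, NA where undefined
      as.numeric((om[-1, , drop = FALSE] - om[-nrow(om), , drop = FALSE]) / dt)
    },
    mu = {
      dV <- V[-1, , , drop = FALSE] - V[-(F - 1), , , drop = FALSE]
      ddV <- dV[-1, , , drop = FALSE] - dV[-(F - 2), , , drop = FALSE]
      as.numeric(sqrt(mag2_matrix(ddV))) / dt^2
    },
    d = as.numeric(nearest_neighbor_matrix(p)$dist),
    eta = {
      nn <- nearest_neighbor_matrix(p[-F, , , drop = FALSE])
      sp <- sqrt(mag2_matrix(V))                 # (F-1) x N speeds
      nsp <- matrix(sp[cbind(rep(seq_len(F - 1), N), as.numeric(nn$index))],
                    F - 1, N)
      e <- (nsp - sp) / nn$dist
      if (!eta_signed) e <- abs(e)
      as.numeric(e)
    })

  values <- values[is.finite(values)]
  structure(list(metric = metric, values = values), class = "metric_samples")
}

# All seven metric sample vectors in one pass (velocities and
# nearest-neighbour tables computed once); numerics identical to
# compute_metric().
trajectory_metric_samples <- function(traj, eta_signed = TRUE) {
  p <- traj$positions
  F <- dim(p)[1]; N <- dim(p)[2]; dt <- traj$dt
  if (F < 4) stop("need >= 4 frames for the full metric set")
  if (N < 2) stop("need >= 2 insects for the full metric set")
  V <- trajectory_velocities(traj)
  A <- (V[-1, , , drop = FALSE] - V[-(F - 1), , , drop = FALSE]) / dt
  om <- angular_velocity_matrix(V, dt)
  dV <- V[-1, , , drop = FALSE] - V[-(F - 1), , , drop = FALSE]
  ddV <- dV[-1, , , drop = FALSE] - dV[-(F - 2), , , drop = FALSE]
  nn <- nearest_neighbor_matrix(p)
  sp <- sqrt(mag2_matrix(V))
  nsp <- matrix(sp[cbind(rep(seq_len(F - 1), N),
                         as.numeric(nn$index[-F, , drop = FALSE]))], F - 1, N)
  eta <- (nsp - sp) / nn$dist[-F, , drop = FALSE]
  if (!eta_signed) eta <- abs(eta)
  out <- list(
    v = as.numeric(sqrt(mag2_matrix(V))),
    a = as.numeric(sqrt(mag2_matrix(A))),
    omega = as.numeric(om),
    alpha = as.numeric((om[-1, , drop = FALSE] - om[-nrow(om), , drop = FALSE]) / dt),
    mu = as.numeric(sqrt(mag2_matrix(ddV))) / dt^2,
    d = as.numeric(nn$dist),
    eta = as.numeric(eta))
  lapply(out, function(x) x[is.finite(x)])
}

# per-frame turning rate; NA where either velocity is (near) zero
angular_velocity_matrix <- function(V, dt) {
  F1 <- dim(V)[1]
  v1 <- V[-F1, , , drop = FALSE]
  v2 <- V[-1, , , drop = FALSE]
  d <- dim(v1)
  dotp <- matrix(v1[, , 1] * v2[, , 1] + v1[, , 2] * v2[, , 2] +
                 v1[, , 3] * v2[, , 3], d[1], d[2])
  n1 <- sqrt(mag2_matrix(v1))
  n2 <- sqrt(mag2_matrix(v2))
  ok <- n1 > 1e-12 & n2 > 1e-12
  arg <- pmin(pmax(dotp / (n1 * n2), -1), 1)
  om <- acos(arg) / dt
  om[!ok] <- NA_real_
  om
}

# nearest-neighbour distance and index per frame: lists of F x N matrices
nearest_neighbor_matrix <- function(p) {
  F <- dim(p)[1]; N <- dim(p)[2]
  dist <- matrix(NA_real_, F, N)
  index <- matrix(NA_integer_, F, N)
  for (t in seq_len(F)) {
    d2 <- pairwise_sq_dist(matrix(p[t, , ], N, 3))
    diag(d2) <- Inf
    index[t, ] <- apply(d2, 1, which.min)
    dist[t, ] <- sqrt(d2[cbind(seq_len(N), index[t, ])])
  }
  list(dist = dist, index = index)
}

#' z-score normalization
#'
#' Mean shift followed by standard-deviation scaling, using the population
#' convention (divide by `n`).  Applied to each dataset separately before
#' distributions are compared, since real and simulated data live on
#' different quantity scales.
#'
#' @param x numeric samples (>= 2 values, non-constant).
#' @return normalized samples (mean 0, population SD 1).
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("zscore needs at least 2 samples")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("zscore: zero variance (degenerate metric)")
  (x - m) / s
}

#' Discrete probability density of metric samples
#'
#' Divides `[u1, u2]` into `M` equal sub-intervals; with `S_i` of the `S`
#' samples in bin `i`, the density there is `Q_i = S_i * M / (S * (u2 - u1))`,
#' so the densities integrate to exactly 1.  Samples outside the interval
#' are clipped into the boundary bins.
#'
#' @param samples numeric vector (non-empty) or a `metric_samples` object.
#' @param M number of bins (>= 1).
#' @param interval numeric length-2, `u2 > u1`.
#' @return object of class `"discrete_pdf"`: list with `u1`, `u2`, `M`,
#'   `densities`, `counts`.
#' @export
discrete_pdf <- function(samples, M = 50L, interval = range(samples)) {
  if (inherits(samples, "metric_samples")) samples <- samples$values
  samples <- as.numeric(samples)
  if (!length(samples)) stop("discrete_pdf: empty samples")
  u1 <- interval[1]; u2 <- interval[2]
  if (!(u2 > u1)) stop("interval must satisfy u2 > u1")
  if (M < 1) stop("M must be >= 1")
  width <- (u2 - u1) / M
  idx <- floor((samples - u1) / width) + 1
  idx <- pmin(pmax(idx, 1), M)          # clip, and put x == u2 in bin M
  counts <- tabulate(idx, nbins = M)
  dens <- counts * M / (length(samples) * (u2 - u1))
  structure(list(u1 = u1, u2 = u2, M = as.integer(M),
                 densities = dens, counts = counts),
            class = "discrete_pdf")
}

#' @export
print.discrete_pdf <- function(x, ...) {
  cat(sprintf("Discrete PDF: %d bins on [%g, %g], integral %.6f\n",
              x$M, x$u1, x$u2, sum(x$densities) * (x$u2 - x$u1) / x$M))
  invisible(x)
}

#' Energy term: L1 distance between two discrete PDFs
#'
#' `raw = sum_i |Q_real,i - Q_sim,i|` over matching bins, then normalized as
#' `E = (raw - p1) / p2`.  With `p1 = 0, p2 = 1` this is the plain L1
#' discrepancy, which is 0 for identical distributions and symmetric in its
#' arguments.
#'
#' @param q_real,q_sim [discrete_pdf()] objects with identical binning.
#' @param p1,p2 normalization parameters (`p2 > 0`).
#' @param on compare the density values (default, as defined) or the per-bin
#'   probabilities (`densities * width`).
#' @return scalar energy.
#' @export
energy_term <- function(q_real, q_sim, p1 = 0, p2 = 1,
                        on = c("density", "probability")) {
  on <- match.arg(on)
  if (q_real$M != q_sim$M || q_real$u1 != q_sim$u1 || q_real$u2 != q_sim$u2)
    stop("energy_term: mismatched binning")
  if (p2 <= 0) stop("p2 must be > 0")
  a <- q_real$densities; b <- q_sim$densities
  if (on == "probability") {
    w <- (q_real$u2 - q_real$u1) / q_real$M
    a <- a * w; b <- b * w
  }
  (sum(abs(a - b)) - p1) / p2
}

#' Weighted evaluation score
#'
#' `E = 1 - sum_phi w_phi E_phi`: 1 means the simulated distributions match
#' the reference exactly (all energies zero); lower is worse.
#'
#' @param energies named numeric vector of per-metric energies.
#' @param weights named numeric vector with the same names.
#' @return scalar score.
#' @export
evaluation_score <- function(energies, weights) {
  if (!setequal(names(energies), names(weights)) || is.null(names(energies)))
    stop("energies and weights must carry the same metric names")
  1 - sum(weights[names(energies)] * energies)
}

#' Compare a simulated trajectory with a reference trajectory
#'
#' The full distributional similarity pipeline for one pair of trajectories:
#' for each of the seven metrics, sample both trajectories, z-score each
#' sample set separately, bin both over the pooled sample range into `M`
#' equal sub-intervals, and take the L1 distance between the two discrete
#' densities; the weighted sum of (normalized) energies is turned into the
#' score `E = 1 - sum w_phi E_phi`.
#'
#' @param reference,sim [swarm_trajectory()] objects (or, for repeated
#'   evaluations against the same data, a named list of precomputed metric
#'   sample vectors with one entry per metric id).
#' @param M number of bins.
#' @param weights named weights over the seven metrics (default equal).
#' @param p1,p2 named vectors of normalization parameters per metric
#'   (defaults 0 and 1).
#' @param zscore_mode `"separate"` (default: each dataset standardized with
#'   its own mean/SD) or `"pooled"`.
#' @param eta_signed see [compute_metric()].
#' @return object of class `"swarm_evaluation"`: energies, raw (pre-`p`)
#'   energies, weights, normalizers and the score.
#' @export
evaluate_swarm <- function(reference, sim, M = 50L, weights = NULL,
                           p1 = NULL, p2 = NULL,
                           zscore_mode = c("separate", "pooled"),
                           eta_signed = TRUE) {
  zscore_mode <- match.arg(zscore_mode)
  ref_samples <- if (inherits(reference, "swarm_trajectory"))
    trajectory_metric_samples(reference, eta_signed) else reference
  sim_samples <- if (inherits(sim, "swarm_trajectory"))
    trajectory_metric_samples(sim, eta_signed) else sim
  ids <- swarm_metric_ids()
  if (is.null(weights)) weights <- stats::setNames(rep(1 / 7, 7), ids)
  if (is.null(p1)) p1 <- stats::setNames(rep(0, 7), ids)
  if (is.null(p2)) p2 <- stats::setNames(rep(1, 7), ids)
  raw <- energies <- stats::setNames(numeric(7), ids)
  for (id in ids) {
    sr <- ref_samples[[id]]
    ss <- sim_samples[[id]]
    if (zscore_mode == "separate") {
      zr <- zscore(sr); zs <- zscore(ss)
    } else {
      z <- zscore(c(sr, ss))
      zr <- z[seq_along(sr)]; zs <- z[-seq_along(sr)]
    }
    rng <- range(c(zr, zs))
    if (rng[2] <= rng[1]) rng <- rng + c(-0.5, 0.5)
    qr <- discrete_pdf(zr, M, rng)
    qs <- discrete_pdf(zs, M, rng)
    raw[id] <- energy_term(qr, qs)
    energies[id] <- (raw[id] - p1[id]) / p2[id]
  }
  structure(list(energies = energies, raw_energies = raw,
                 weights = weights[ids], p1 = p1[ids], p2 = p2[ids],
                 score = evaluation_score(energies, weights[ids])),
            class = "swarm_evaluation")
}

#' @export
print.swarm_evaluation <- function(x, ...) {
  cat("Swarm evaluation\n")
  tab <- rbind(energy = x$energies, weight = x$weights)
  print(round(tab, 4))
  cat(sprintf("score E = %.4f\n", x$score))
  invisible(x)
}

#' Entropy-based objective weights for the energy terms
#'
#' Given the energy matrix `X` (one row per compared model, one column per
#' metric), each column is min-max normalized
#' (`p1_j = min_i x_ij`, `p2_j = max_i x_ij - min_i x_ij`), converted to the
#' "goodness" distribution `g_ij = r_ij / sum_i r_ij` with `r_ij = 1 - x_ij`,
#' and scored by its normalized Shannon entropy
#' `e_j = -(1/ln m) sum_i g_ij ln g_ij` (with `0 ln 0 = 0`).  Metrics whose
#' energies discriminate strongly among the models have low entropy and
#' receive large weights `w_j = (1 - e_j) / sum_j (1 - e_j)`.
#'
#' A constant column cannot discriminate: it is assigned entropy 1, hence
#' weight 0.  If every column is constant there is no discriminating term
#' and an error is raised.
#'
#' @param X numeric matrix, `m >= 2` models by `n` energy terms.
#' @return list with `weights` (sums to 1, non-negative), `p1`, `p2`
#'   (per-column normalizers; `p2 = 0` marks a degenerate column) and
#'   `entropy`.
#' @export
entropy_weights <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X); n <- ncol(X)
  if (m < 2) stop("entropy weighting needs at least 2 models")
  p1 <- apply(X, 2, min)
  p2 <- apply(X, 2, max) - p1
  e <- numeric(n)
  for (j in seq_len(n)) {
    if (p2[j] == 0) { e[j] <- 1; next }     # non-discriminating term
    x <- (X[, j] - p1[j]) / p2[j]
    r <- 1 - x
    if (sum(r) == 0) { e[j] <- 1; next }    # all models at the worst value
    g <- r / sum(r)
    gl <- ifelse(g > 0, g * log(g), 0)
    e[j] <- -sum(gl) / log(m)
  }
  if (all(e >= 1 - 1e-12)) stop("no discriminating energy term (all entropies 1)")
  w <- (1 - e) / sum(1 - e)
  names(w) <- names(e) <- names(p1) <- names(p2) <- colnames(X)
  list(weights = w, p1 = p1, p2 = p2, entropy = e)
}
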