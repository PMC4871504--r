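# Independent oracles used across the tests.  These re-derive quantities
# with deliberately naive code (scalar double loops, closed forms, dense
# sampling) so they share no code path with the package implementation.

# literal double-loop evaluation of the zonal interaction force
brute_force_interaction <- function(i, pos, vel, p) {
  total <- c(0, 0, 0)
  zones <- list(rep = c(0, p$r_rep, p$chi_rep, -1),
                ali = c(p$r_rep, p$r_ali, p$chi_ali, 0),
                att = c(p$r_ali, p$r_att, p$chi_att, 1))
  for (z in zones) {
    acc <- c(0, 0, 0); nk <- 0
    for (j in seq_len(nrow(pos))) {
      if (j == i) next
      dvec <- pos[j, ] - pos[i, ]
      dist <- sqrt(sum(dvec^2))
      if (dist > p$r_att) next
      in_zone <- if (z[4] == 1) dist >= z[1] && dist <= z[2]
                 else dist >= z[1] && dist < z[2]
      if (!in_zone) next
      nk <- nk + 1
      g <- z[4]
      rhat <- dvec / dist
      wvec <- vel[j, ] - vel[i, ]
      wn <- sqrt(sum(wvec^2))
      vhat <- if (wn > 1e-12) wvec / wn else c(0, 0, 0)
      acc <- acc + g * rhat + (1 - abs(g)) * vhat
    }
    if (nk > 0) total <- total + z[3] * acc / nk
  }
  total
}

# minimum pairwise distance in a position matrix
min_pair_dist <- function(pos) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  min(d)
}

# minimum separation of two agents moving linearly over a time horizon
# (closed form: |relp + relv t| is minimized at the clamped critical t)
min_linear_separation <- function(p1, v1, p2, v2, horizon) {
  relp <- p2 - p1; relv <- v2 - v1
  vv <- sum(relv^2)
  t_star <- if (vv > 0) max(0, min(horizon, -sum(relp * relv) / vv)) else 0
  sqrt(sum((relp + relv * t_star)^2))
}

# same, vectorised over an n x 3 matrix of candidate velocities for agent 1
min_linear_separation_grid <- function(p1, cand_v1, p2, v2, horizon) {
  relp <- matrix(p2 - p1, nrow(cand_v1), 3, byrow = TRUE)
  relv <- matrix(v2, nrow(cand_v1), 3, byrow = TRUE) - cand_v1
  vv <- rowSums(relv^2)
  ts <- ifelse(vv > 0, pmax(0, pmin(horizon, -rowSums(relp * relv) / vv)), 0)
  sqrt(rowSums((relp + relv * ts)^2))
}

# non-overlapping jittered grid of n points with spacing `pitch`
grid_positions <- function(n, pitch, jitter = 0.1 * pitch) {
  side <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))[seq_len(n), ] * pitch
  g + matrix(stats::runif(n * 3, -jitter, jitter), n, 3)
}

# the midge-like generating model used by recovery/ablation experiments
fixture_config <- function(n_insects, n_frames, seed) {
  swarmsim:::swarmlike_config(n_insects, n_frames, 1 / 60, seed)
}
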