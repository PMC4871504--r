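#' Swarm trajectory object
#'
#' A frame-indexed record of 3D positions for every insect at a fixed time
#' step: the common currency between the simulator, the evaluation metrics
#' and the parameter estimator.  Real motion-capture datasets and synthetic
#' fixtures are represented the same way.
#'
#' @param positions numeric array `frames x insects x 3`.
#' @param dt time step between frames (time units).
#' @param metadata optional named list (scenario, seed, parameters, per-frame
#'   logs...).
#' @return An object of class `"swarm_trajectory"`.
#' @export
swarm_trajectory <- function(positions, dt, metadata = list()) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 3, dt > 0)
  if (any(!is.finite(positions))) stop("trajectory contains non-finite positions")
  structure(list(positions = positions, dt = as.numeric(dt),
                 metadata = metadata),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("Swarm trajectory: %d frames x %d insects, dt = %g\n",
              d[1], d[2], x$dt))
  if (!is.null(x$metadata$scenario))
    cat("  scenario:", x$metadata$scenario, "\n")
  if (!is.null(x$metadata$seed))
    cat("  seed:", x$metadata$seed, "\n")
  invisible(x)
}

#' @export
#' @param y ignored.
#' @param dims which two coordinate axes to draw (default x against y).
#' @param max_insects draw at most this many paths.
#' @rdname swarm_trajectory
plot.swarm_trajectory <- function(x, y, dims = c(1, 2), max_insects = 20, ...) {
  p <- x$positions
  n <- min(dim(p)[2], max_insects)
  labs <- c("x", "y", "z")[dims]
  graphics::matplot(p[, seq_len(n), dims[1]], p[, seq_len(n), dims[2]],
                    type = "l", lty = 1, xlab = labs[1], ylab = labs[2],
                    main = "Swarm trajectories", ...)
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]
n_insects <- function(traj) dim(traj$positions)[2]

#' Write / read a trajectory as a columnar text file
#'
#' The file holds an optional `# dt <value>` comment, a header line, then
#' one row per (frame, insect): `frame insect x y z`, with positions printed
#' to full double precision so that a write/read round trip is lossless.
#'
#' @param traj a [swarm_trajectory()].
#' @param path file path.
#' @return `read_trajectory()` returns a [swarm_trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  p <- traj$positions
  d <- dim(p)
  frame <- rep(seq_len(d[1]), each = d[2])
  insect <- rep(seq_len(d[2]), times = d[1])
  # flatten frame-major: row (f, i)
  xyz <- matrix(aperm(p, c(2, 1, 3)), d[1] * d[2], 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt %.17g", traj$dt), con)
  writeLines("frame insect x y z", con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g",
                     frame, insect, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @param dt fallback time step if the file carries none.
#' @export
read_trajectory <- function(path, dt = 1 / 60) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  offset <- 0L
  if (startsWith(lines[1], "# dt")) {
    dt <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][3])
    offset <- 1L
  }
  if (lines[offset + 1L] != "frame insect x y z")
    stop("missing header line in ", path)
  body <- lines[-seq_len(offset + 1L)]
  body <- body[nzchar(body)]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 5L)
  if (length(bad))
    stop(sprintf("malformed trajectory row at line %d of %s (%d fields, expected 5)",
                 bad[1] + offset + 1L, path, nf[bad[1]]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE)
  if (any(!is.finite(m)))
    stop(sprintf("non-numeric value at line %d of %s",
                 which(rowSums(!is.finite(m)) > 0)[1] + offset + 1L, path))
  frames <- sort(unique(m[, 1]))
  ids <- sort(unique(m[, 2]))
  F <- length(frames); N <- length(ids)
  if (nrow(m) != F * N)
    stop("trajectory file is not a complete frame x insect grid: ", path)
  p <- array(NA_real_, c(F, N, 3))
  fi <- match(m[, 1], frames)
  ii <- match(m[, 2], ids)
  for (k in 1:3) p[cbind(fi, ii, k)] <- m[, k + 2]
  swarm_trajectory(p, dt)
}

#' Polarization order parameter of a set of velocities
#'
#' `| sum_i v_i / |v_i| | / N`, the norm of the mean heading: 0 for a fully
#' disordered swarm, 1 for a perfectly aligned flock.  Insects with (near)
#' zero speed carry no heading and are excluded from the mean.
#'
#' @param v an `n x 3` matrix of velocities.
#' @return scalar in `[0, 1]` (`NA` if no insect is moving).
#' @export
polarization <- function(v) {
  v <- as_position_matrix(v)
  sp <- sqrt(rowSums(v^2))
  keep <- sp > 1e-12
  if (!any(keep)) return(NA_real_)
  u <- v[keep, , drop = FALSE] / sp[keep]
  sqrt(sum(colSums(u)^2)) / sum(keep)
}

#' Per-frame polarization of a trajectory
#'
#' Headings are taken from forward-difference velocities, so the series has
#' `frames - 1` entries.
#'
#' @param traj a [swarm_trajectory()].
#' @return numeric vector of length `frames - 1`.
#' @export
trajectory_polarization <- function(traj) {
  p <- traj$positions
  F <- dim(p)[1]
  vapply(seq_len(F - 1), function(t) {
    polarization((p[t + 1, , ] - p[t, , ]) / traj$dt)
  }, numeric(1))
}
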