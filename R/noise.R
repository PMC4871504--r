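#' Specification of the inherent-noise force field
#'
#' The stochastic force modelling the random, noise-induced component of
#' insect flight.  Four candidate generators are supported:
#' \describe{
#'   \item{`white`}{three independent uniform deviates on `[-1, 1]`, scaled
#'     by `gain`.}
#'   \item{`gaussian`}{Gaussian white noise built from two uniform deviates
#'     per component, `G = lambda * sqrt(-2 log W1) * sin(2 pi W2)` (the
#'     Box-Muller transform, so each component is exactly
#'     `N(0, lambda^2)`).}
#'   \item{`perlin`}{a smooth vector field of three independent gradient-noise
#'     channels evaluated at the insect's position: spatially correlated,
#'     deterministic in `(position, seed)`.}
#'   \item{`curl`}{the curl of the Perlin vector potential: a divergence-free
#'     (incompressible) swirling field, also deterministic in
#'     `(position, seed)`.}
#' }
#'
#' @param kind one of `"white"`, `"gaussian"`, `"perlin"`, `"curl"`.
#' @param lambda strength of the Gaussian component (>= 0).
#' @param scale spatial smoothness (> 0); positions are divided by `scale`.
#' @param gain output magnitude (>= 0).
#' @param seed integer seed of the gradient-noise lattice.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("curl", "perlin", "white", "gaussian"),
                       lambda = 1, scale = 1, gain = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (scale <= 0) stop("scale must be > 0")
  if (gain < 0 || lambda < 0) stop("gain and lambda must be >= 0")
  structure(list(kind = kind, lambda = as.numeric(lambda),
                 scale = as.numeric(scale), gain = as.numeric(gain),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' White noise force samples
#'
#' `n` independent 3-vectors with components uniform on `[-1, 1]`
#' (zero mean, variance 1/3 per component).  Draws come from R's global RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param n number of 3-vectors.
#' @return an `n x 3` numeric matrix.
#' @export
white_noise <- function(n = 1L) {
  matrix(stats::runif(3L * n, -1, 1), n, 3L)
}

#' Gaussian white noise force samples
#'
#' Each component is `lambda * sqrt(-2 log W1) * sin(2 pi W2)` with
#' `W1 ~ U(0, 1]` and `W2 ~ U[0, 1)`: the Box-Muller transform, hence an
#' exact `N(0, lambda^2)` deviate.
#'
#' @param lambda strength coefficient (>= 0).
#' @param n number of 3-vectors.
#' @return an `n x 3` numeric matrix.
#' @export
gaussian_white_noise <- function(lambda = 1, n = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  w1 <- 1 - stats::runif(3L * n)    # strictly in (0, 1]
  w2 <- stats::runif(3L * n)
  matrix(lambda * sqrt(-2 * log(w1)) * sin(2 * pi * w2), n, 3L)
}

# Fixed sampling offsets making three scalar channels out of one gradient
# noise instance.  Large and incommensurate so the channels are effectively
# independent.
.perlin_channel_offsets <- matrix(c(
    0.0,    0.0,    0.0,
  101.9,   47.3,  -13.7,
  -63.1,  157.5,   87.2), nrow = 3, byrow = TRUE)

# Deterministic permutation table for the gradient lattice, derived from the
# seed with a small LCG (independent of R's RNG state).
perlin_permutation <- function(seed) {
  s <- as.double(seed %% 2^31)
  nxt <- function() {
    s <<- (69069 * s + 1) %% 2^32
    s
  }
  p <- 0:255
  for (i in 256:2) {               # Fisher-Yates
    j <- (nxt() %% i) + 1
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  }
  c(p, p)                          # doubled to avoid index wrapping
}

perm_cache <- new.env(parent = emptyenv())

get_permutation <- function(seed) {
  key <- as.character(as.integer(seed))
  if (is.null(perm_cache[[key]])) perm_cache[[key]] <- perlin_permutation(seed)
  perm_cache[[key]]
}

# Classic improved gradient noise, vectorised over points.  Value is 0 at
# every integer lattice point and C2-continuous in between; range ~[-1, 1].
perlin3 <- function(x, y, z, perm) {
  xi <- floor(x); yi <- floor(y); zi <- floor(z)
  xf <- x - xi; yf <- y - yi; zf <- z - zi
  X <- as.integer(xi %% 256); Y <- as.integer(yi %% 256); Z <- as.integer(zi %% 256)

  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(xf); v <- fade(yf); w <- fade(zf)

  # hash the 8 cube corners (perm is 1-based in R)
  A  <- perm[X + 1L] + Y
  AA <- perm[A + 1L] + Z
  AB <- perm[A + 2L] + Z
  B  <- perm[X + 2L] + Y
  BA <- perm[B + 1L] + Z
  BB <- perm[B + 2L] + Z

  # gradient table of the classic 12-direction set (4 repeats), indexed by
  # the low 4 bits of the corner hash
  gx <- c(1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0, 1, 0, -1, 0)
  gy <- c(1, 1, -1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1)
  gz <- c(0, 0, 0, 0, 1, 1, -1, -1, 1, 1, -1, -1, 0, 1, 0, -1)
  grad <- function(hash, x, y, z) {
    h <- hash %% 16L + 1L
    gx[h] * x + gy[h] * y + gz[h] * z
  }
  lerp <- function(t, a, b) a + t * (b - a)

  lerp(w,
       lerp(v,
            lerp(u, grad(perm[AA + 1L], xf,     yf,     zf),
                    grad(perm[BA + 1L], xf - 1, yf,     zf)),
            lerp(u, grad(perm[AB + 1L], xf,     yf - 1, zf),
                    grad(perm[BB + 1L], xf - 1, yf - 1, zf))),
       lerp(v,
            lerp(u, grad(perm[AA + 2L], xf,     yf,     zf - 1),
                    grad(perm[BA + 2L], xf - 1, yf,     zf - 1)),
            lerp(u, grad(perm[AB + 2L], xf,     yf - 1, zf - 1),
                    grad(perm[BB + 2L], xf - 1, yf - 1, zf - 1))))
}

#' Smooth gradient-noise (Perlin) force field
#'
#' Evaluates the three-channel gradient-noise vector field at one or more
#' positions: `P(r) = gain * (P1(r/scale), P2(r/scale), P3(r/scale))` where
#' the channels are one seeded gradient-noise instance sampled at three
#' fixed, well-separated coordinate offsets.  The field is a pure function
#' of `(position, seed)`, continuous in position, and zero at the (offset)
#' lattice points of each channel.
#'
#' @param r positions: a 3-vector or an `n x 3` matrix.
#' @param spec a [noise_spec()].
#' @return same shape as `r` (3-vector or `n x 3` matrix).
#' @export
perlin_field <- function(r, spec) {
  single <- !is.matrix(r)
  r <- if (single) matrix(as.numeric(r), 1, 3) else as_position_matrix(r)
  perm <- get_permutation(spec$seed)
  p <- r / spec$scale
  out <- matrix(0, nrow(r), 3)
  for (k in 1:3) {
    off <- .perlin_channel_offsets[k, ]
    out[, k] <- perlin3(p[, 1] + off[1], p[, 2] + off[2], p[, 3] + off[3], perm)
  }
  out <- out * spec$gain
  if (single) out[1, ] else out
}

#' Divergence-free curl-noise force field
#'
#' The curl of the gradient-noise vector potential, `C(r) = curl P(r)`,
#' evaluated by central finite differences with step `h` (default
#' `1e-4 * scale`).  Because it is a curl, the field is incompressible
#' (zero divergence) up to discretisation error, producing swirling,
#' volume-preserving perturbations rather than sources or sinks.
#'
#' @param r positions: a 3-vector or an `n x 3` matrix.
#' @param spec a [noise_spec()].
#' @param h finite-difference step.
#' @param potential optional override of the vector potential for testing:
#'   a function mapping an `n x 3` position matrix to an `n x 3` matrix.
#'   Defaults to the Perlin field of `spec`.
#' @return same shape as `r`.
#' @export
curl_field <- function(r, spec, h = 1e-4 * spec$scale, potential = NULL) {
  single <- !is.matrix(r)
  r <- if (single) matrix(as.numeric(r), 1, 3) else as_position_matrix(r)
  P <- if (is.null(potential)) function(x) perlin_field(x, spec) else potential
  n <- nrow(r)
  shift <- function(dim, s) {
    rr <- r
    rr[, dim] <- rr[, dim] + s
    P(rr)
  }
  # dP/dx, dP/dy, dP/dz, each n x 3
  dPdx <- (shift(1, h) - shift(1, -h)) / (2 * h)
  dPdy <- (shift(2, h) - shift(2, -h)) / (2 * h)
  dPdz <- (shift(3, h) - shift(3, -h)) / (2 * h)
  out <- cbind(dPdy[, 3] - dPdz[, 2],
               dPdz[, 1] - dPdx[, 3],
               dPdx[, 2] - dPdy[, 1])
  if (single) out[1, ] else out
}

#' Numerical divergence of a noise field
#'
#' Central-difference estimate of `div F` at the given points; used to check
#' the incompressibility of the curl field.
#'
#' @param r an `n x 3` matrix of positions.
#' @param field function mapping an `n x 3` matrix to an `n x 3` matrix.
#' @param h finite-difference step.
#' @return numeric vector of length `n`.
#' @export
field_divergence <- function(r, field, h) {
  r <- as_position_matrix(r)
  div <- numeric(nrow(r))
  for (dim in 1:3) {
    rp <- r; rp[, dim] <- rp[, dim] + h
    rm <- r; rm[, dim] <- rm[, dim] - h
    div <- div + (field(rp)[, dim] - field(rm)[, dim]) / (2 * h)
  }
  div
}

# Noise force for all insects at one time step, dispatching on spec$kind.
noise_forces <- function(positions, spec) {
  n <- nrow(positions)
  switch(spec$kind,
    white    = spec$gain * white_noise(n),
    gaussian = gaussian_white_noise(spec$lambda, n),
    perlin   = perlin_field(positions, spec),
    curl     = curl_field(positions, spec))
}
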