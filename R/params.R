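#' Model parameters for the swarm dynamics model
#'
#' Constructs and validates the 11-parameter set governing the force-based
#' dynamics: friction, the two noise-field parameters, and the weight/radius
#' pairs of the four behavioural forces (repulsion, alignment, attraction,
#' stimulus response).
#'
#' The three interaction radii delimit concentric spherical zones around each
#' insect and must satisfy `r_att >= r_ali >= r_rep >= 0`.  Configurations may
#' alternatively specify the radii as successive differences
#' (`r_ali_diff = r_ali - r_rep`, `r_att_diff = r_att - r_ali`), the
#' convention used when radii are reported relative to the inner zones; set
#' `radii = "diff"` to interpret `r_ali`/`r_att` that way.  Internally radii
#' are always stored absolute.
#'
#' @param gamma friction coefficient (>= 0); drag force is `-gamma*|v|*v`
#'   by default (see [friction_force()]).
#' @param scale spatial smoothness of the noise field (> 0); positions are
#'   divided by `scale` before sampling the gradient noise, so larger values
#'   give smoother, lower-frequency noise.
#' @param gain magnitude of the noise force (>= 0).
#' @param chi_rep,chi_ali,chi_att,chi_res non-negative force weights.
#' @param r_rep,r_ali,r_att interaction zone radii (world length units).
#' @param r_res visual range for stimulus response (>= 0).
#' @param radii `"absolute"` (default) or `"diff"` (radius differences).
#' @return An object of class `"swarm_params"` (a named list of the 11
#'   parameters, radii stored absolute).
#' @seealso [read_params()], [write_params()]
#' @export
swarm_params <- function(gamma = 0, scale = 1, gain = 0,
                         chi_rep = 0, r_rep = 0,
                         chi_ali = 0, r_ali = 0,
                         chi_att = 0, r_att = 0,
                         chi_res = 0, r_res = 0,
                         radii = c("absolute", "diff")) {
  radii <- match.arg(radii)
  if (radii == "diff") {
    r_ali <- r_rep + r_ali
    r_att <- r_ali + r_att
  }
  p <- list(gamma = gamma, scale = scale, gain = gain,
            chi_rep = chi_rep, r_rep = r_rep,
            chi_ali = chi_ali, r_ali = r_ali,
            chi_att = chi_att, r_att = r_att,
            chi_res = chi_res, r_res = r_res)
  p <- lapply(p, as.numeric)
  class(p) <- "swarm_params"
  validate_swarm_params(p)
  p
}

validate_swarm_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("gamma", "scale", "gain", "chi_rep", "r_rep", "chi_ali", "r_ali",
            "chi_att", "r_att", "chi_res", "r_res")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("swarm_params missing fields: ", paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (!all(is.finite(vals)))
    stop("swarm_params must be finite")
  if (p$scale <= 0) stop("scale must be > 0")
  if (any(vals[c("gamma", "gain", "chi_rep", "chi_ali", "chi_att", "chi_res",
                 "r_res")] < 0))
    stop("gamma, gain, force weights and r_res must be >= 0")
  if (!(p$r_att >= p$r_ali && p$r_ali >= p$r_rep && p$r_rep >= 0))
    stop("zone radii must satisfy r_att >= r_ali >= r_rep >= 0")
  invisible(p)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("Swarm dynamics parameters:\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' @export
as.list.swarm_params <- function(x, ...) unclass(x)

#' An environmental stimulus (predator or pursuit target)
#'
#' @param position 3-vector, world coordinates of the stimulus.  May also be
#'   a function `f(frame, time)` returning a 3-vector for moving stimuli.
#' @param kind `"predator"` (escape response) or `"target"` (pursuit).
#' @param from,to first and last simulation frame (1-based) during which the
#'   stimulus is active; defaults to always active.
#' @return An object of class `"stimulus"`.
#' @export
stimulus <- function(position, kind = c("target", "predator"),
                     from = 1L, to = Inf) {
  kind <- match.arg(kind)
  if (!is.function(position)) {
    position <- as.numeric(position)
    stopifnot(length(position) == 3, all(is.finite(position)))
  }
  structure(list(position = position,
                 kind = kind,
                 s_e = if (kind == "predator") 1L else 0L,
                 from = from, to = to),
            class = "stimulus")
}

stimulus_position <- function(stim, frame, time) {
  if (is.function(stim$position)) as.numeric(stim$position(frame, time))
  else stim$position
}

stimulus_active <- function(stim, frame) {
  frame >= stim$from && frame <= stim$to
}

#' Read / write model parameters as a flat key-value config file
#'
#' The on-disk format is flat YAML with keys named exactly
#' `gamma, scale, gain, chi_rep, r_rep, chi_ali, r_ali, chi_att, r_att,
#' chi_res, r_res`.  Noise settings, when present, live under the keys
#' `noise.kind`, `noise.lambda` and `noise.seed` (see [noise_spec()]).
#'
#' @param path file path.
#' @param params a [swarm_params()] object.
#' @param noise optional [noise_spec()] serialized alongside the parameters.
#' @return `read_params()` returns a list with elements `params`
#'   (`swarm_params`) and `noise` (`noise_spec` or `NULL`);
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path, noise = NULL) {
  validate_swarm_params(params)
  out <- lapply(unclass(params), as.numeric)
  if (!is.null(noise)) {
    out[["noise.kind"]] <- noise$kind
    out[["noise.lambda"]] <- noise$lambda
    out[["noise.scale"]] <- noise$scale
    out[["noise.gain"]] <- noise$gain
    out[["noise.seed"]] <- noise$seed
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  keys <- c("gamma", "scale", "gain", "chi_rep", "r_rep", "chi_ali", "r_ali",
            "chi_att", "r_att", "chi_res", "r_res")
  miss <- setdiff(keys, names(raw))
  if (length(miss))
    stop("config file missing keys: ", paste(miss, collapse = ", "))
  p <- do.call(swarm_params, raw[keys])
  ns <- NULL
  if (!is.null(raw[["noise.kind"]])) {
    ns <- noise_spec(kind = raw[["noise.kind"]],
                     lambda = raw[["noise.lambda"]] %||% 1,
                     scale = raw[["noise.scale"]] %||% p$scale,
                     gain = raw[["noise.gain"]] %||% p$gain,
                     seed = raw[["noise.seed"]] %||% 1L)
  }
  list(params = p, noise = ns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
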