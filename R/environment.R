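## Synthetic generative environments R: branching sequence graphs emitting
## noisy vector stimuli. Branching is realized as a tree of sequences -
## sequences share a prefix up to each branch position and diverge into
## `branch_arity` suffixes - which matches the memorized-possibilities
## picture the agent conditions on. Sensory noise is drawn from a private
## RNG stream (independent of the episode seed) so noise invariance can be
## probed by varying only the noise seed.

#' Environment specification
#'
#' @param n_sequences number of independent trunks (sequence families).
#' @param seq_length states per sequence.
#' @param branch_positions 1-based positions after which sequences diverge
#'   (`branch_positions < seq_length`); each listed position is a
#'   `branch_arity`-way branch point.
#' @param branch_arity nu, the number of alternatives at each branch
#'   (`>= 2`).
#' @param branch_probs probabilities over the nu alternatives (default
#'   uniform).
#' @param dim stimulus dimension d.
#' @param min_separation minimum pairwise Euclidean distance between state
#'   prototypes (must be positive; keeps the known/new dichotomy
#'   well-defined).
#' @param noise_sd standard deviation of the isotropic Gaussian emission
#'   noise.
#' @param novelty_rate per-step probability of injecting a brand-new stimulus
#'   prototype.
#' @param seed structural seed: prototypes and topology are a pure function
#'   of the spec including this seed.
#' @param novelty_persistent whether injected novel prototypes persist as new
#'   environment states (default) or are transient one-off stimuli.
#' @return an object of class `env_spec`.
#' @export
env_spec <- function(n_sequences = 1, seq_length = 8, branch_positions = integer(0),
                     branch_arity = 2, branch_probs = NULL, dim = 8,
                     min_separation = 1, noise_sd = 0.02, novelty_rate = 0,
                     seed = 1, novelty_persistent = TRUE) {
  spec <- list(n_sequences = as.integer(n_sequences),
               seq_length = as.integer(seq_length),
               branch_positions = as.integer(branch_positions),
               branch_arity = as.integer(branch_arity),
               branch_probs = branch_probs, dim = as.integer(dim),
               min_separation = min_separation, noise_sd = noise_sd,
               novelty_rate = novelty_rate, seed = as.integer(seed),
               novelty_persistent = isTRUE(novelty_persistent))
  if (spec$n_sequences < 1 || spec$seq_length < 2) stopf("need >= 1 sequence of length >= 2")
  if (length(spec$branch_positions)) {
    if (spec$branch_arity < 2) stopf("branch_arity must be >= 2")
    if (any(spec$branch_positions < 1 | spec$branch_positions >= spec$seq_length))
      stopf("branch_positions must lie in [1, seq_length)")
    if (anyDuplicated(spec$branch_positions)) stopf("duplicate branch positions")
  }
  if (is.null(spec$branch_probs))
    spec$branch_probs <- rep(1 / spec$branch_arity, spec$branch_arity)
  if (length(spec$branch_probs) != spec$branch_arity ||
      abs(sum(spec$branch_probs) - 1) > 1e-9 || any(spec$branch_probs < 0))
    stopf("branch_probs must be a distribution over branch_arity alternatives")
  if (spec$min_separation <= 0) stopf("min_separation must be positive")
  if (spec$noise_sd < 0) stopf("noise_sd must be non-negative")
  if (spec$novelty_rate < 0 || spec$novelty_rate > 1) stopf("novelty_rate must be in [0,1]")
  structure(spec, class = "env_spec")
}

## Draw one prototype at pairwise separation >= sep from rows of `existing`,
## by rejection sampling in a hypercube sized to the state count.
draw_separated <- function(existing, d, sep, n_target) {
  L <- sep * max(2, ceiling((3 * max(n_target, nrow(existing) + 1))^(1 / d)))
  for (try in 1:500) {
    cand <- stats::runif(d, -L, L)
    if (nrow(existing) == 0L) return(cand)
    d2 <- rowSums((existing - matrix(cand, nrow(existing), d, byrow = TRUE))^2)
    if (min(d2) >= sep^2) return(cand)
  }
  stopf("could not place prototypes at separation %.3g in dimension %d; increase dim or reduce the state count", sep, d)
}

## Rebuild successor structure, starts and hash from paths + weights.
env_finalize <- function(env) {
  n <- nrow(env$proto)
  succ <- vector("list", n); succ_w <- vector("list", n)
  start_w <- numeric(0); starts <- integer(0)
  for (k in seq_along(env$seq_paths)) {
    p <- env$seq_paths[[k]]; w <- env$path_w[k]
    i <- match(p[1], starts)
    if (is.na(i)) { starts <- c(starts, p[1]); start_w <- c(start_w, w) }
    else start_w[i] <- start_w[i] + w
    if (length(p) > 1) for (j in seq_len(length(p) - 1L)) {
      a <- p[j]; b <- p[j + 1L]
      i <- match(b, succ[[a]])
      if (is.na(i)) { succ[[a]] <- c(succ[[a]], b); succ_w[[a]] <- c(succ_w[[a]], w) }
      else succ_w[[a]][i] <- succ_w[[a]][i] + w
    }
  }
  env$succ <- succ
  env$succ_prob <- lapply(succ_w, function(w) if (length(w)) w / sum(w) else numeric(0))
  env$starts <- starts
  env$start_probs <- start_w / sum(start_w)
  env$n_base <- n
  env$novel_resume <- stats::setNames(integer(0), character(0))
  env
}

#' Generate a branching sequence environment
#'
#' Deterministic given the spec (including its seed): prototypes are drawn by
#' rejection sampling until the pairwise separation invariant holds, and the
#' sequence tree is laid out per the branch positions. The caller's RNG state
#' is left untouched.
#'
#' @param spec an [env_spec()].
#' @return an object of class `env_model`: a directed graph of emitting
#'   states with prototype matrix `proto`, successor structure, start states,
#'   the full registered sequence paths `seq_paths` with weights, and a
#'   private sensory-noise RNG stream.
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "env_spec"))
  bp <- sort(spec$branch_positions)
  nb <- length(bp)
  nu <- spec$branch_arity
  key2id <- new.env(parent = emptyenv())
  labels <- character(0)
  paths <- list(); path_w <- numeric(0)
  n_states <- 0L
  variants <- if (nb > 0) as.matrix(expand.grid(rep(list(seq_len(nu)), nb))) else matrix(0L, 1, 0)
  for (trunk in seq_len(spec$n_sequences)) {
    for (v in seq_len(nrow(variants))) {
      choice <- variants[v, ]
      path <- integer(spec$seq_length)
      w <- 1 / spec$n_sequences
      if (nb > 0) w <- w * prod(spec$branch_probs[choice])
      for (i in seq_len(spec$seq_length)) {
        rel <- which(bp < i)  # branches already passed at position i
        key <- paste(trunk, i, paste(choice[rel], collapse = "."), sep = "|")
        id <- key2id[[key]]
        if (is.null(id)) {
          n_states <- n_states + 1L
          id <- n_states
          key2id[[key]] <- id
          labels[id] <- paste0("t", trunk, "p", i,
                               if (length(rel)) paste0("b", paste(choice[rel], collapse = ".")) else "")
        }
        path[i] <- id
      }
      paths[[length(paths) + 1L]] <- path
      path_w <- c(path_w, w)
    }
  }
  proto <- with_rng_stream(NULL, spec$seed, {
    m <- matrix(numeric(0), 0, spec$dim)
    for (i in seq_len(n_states))
      m <- rbind(m, draw_separated(m, spec$dim, spec$min_separation, n_states))
    m
  })$value
  env <- structure(list(
    dim = spec$dim, proto = proto, labels = labels,
    seq_paths = paths, path_w = path_w / sum(path_w),
    noise_sd = spec$noise_sd, novelty_rate = spec$novelty_rate,
    min_sep = spec$min_separation,
    novelty_persistent = spec$novelty_persistent,
    deprivation = FALSE,
    noise_seed = (spec$seed + 104729L) %% .Machine$integer.max,
    noise_state = NULL,
    transient_resume = NA_integer_, transient_n = 0L,
    spec = spec
  ), class = "env_model")
  env_finalize(env)
}

#' Sensory-deprivation environment
#'
#' An environment with no learned structure at all: a single self-looping
#' state at the origin whose emissions are pure endogenous noise vectors, so
#' at any ordinary novelty radius every emission classifies as new. The
#' fraction of emissions with norm exceeding a radius eps follows the
#' chi-square tail `1 - pchisq((eps/sd)^2, dim)`.
#'
#' @param dim stimulus dimension.
#' @param noise_sd_endo standard deviation of the endogenous noise (must be
#'   positive).
#' @param seed structural seed (drives the private noise stream).
#' @return an `env_model`.
#' @export
deprivation_environment <- function(dim = 8, noise_sd_endo = 1, seed = 1) {
  stopifnot(noise_sd_endo > 0)
  env <- structure(list(
    dim = as.integer(dim), proto = matrix(0, 1, dim), labels = "endo",
    seq_paths = list(c(1L)), path_w = 1,
    noise_sd = noise_sd_endo, novelty_rate = 0, min_sep = 0,
    novelty_persistent = TRUE, deprivation = TRUE,
    noise_seed = (as.integer(seed) + 104729L) %% .Machine$integer.max,
    noise_state = NULL, transient_resume = NA_integer_, transient_n = 0L,
    spec = NULL
  ), class = "env_model")
  env <- env_finalize(env)
  env$succ[[1]] <- 1L; env$succ_prob[[1]] <- 1  # self-loop: deprivation persists
  env
}

#' @export
print.env_model <- function(x, ...) {
  cat("<env_model: ", nrow(x$proto), " states (dim ", x$dim, "), ",
      length(x$seq_paths), " sequences, noise_sd ", x$noise_sd,
      ", novelty_rate ", x$novelty_rate,
      if (x$deprivation) ", deprivation regime" else "", ">\n", sep = "")
  invisible(x)
}

#' Number of states in an environment
#' @param env an `env_model`.
#' @export
n_env_states <- function(env) nrow(env$proto)

#' Reseed the private sensory-noise stream
#'
#' Emission noise is drawn from an RNG stream independent of the episode
#' seed; changing only this seed changes only the sensory noise, leaving the
#' trajectory, novelty events and threshold draws of a seeded episode intact.
#'
#' @param env an `env_model`.
#' @param seed integer noise seed.
#' @return the updated environment.
#' @export
set_noise_seed <- function(env, seed) {
  env$noise_seed <- as.integer(seed)
  env$noise_state <- NULL
  env
}

#' Emit a stimulus from an environment state
#'
#' Prototype plus isotropic Gaussian noise of sd `noise_sd`, drawn from the
#' environment's private noise stream (which advances: the updated
#' environment is returned alongside the stimulus).
#'
#' @param env an `env_model`.
#' @param state state id.
#' @return list with `env` (noise stream advanced) and `stimulus`.
#' @export
emit <- function(env, state) {
  stopifnot(inherits(env, "env_model"))
  if (state < 1 || state > nrow(env$proto)) stopf("state %s not in environment", state)
  base <- env$proto[state, ]
  if (env$noise_sd == 0) return(list(env = env, stimulus = base))
  res <- with_rng_stream(env$noise_state, env$noise_seed,
                         stats::rnorm(env$dim, 0, env$noise_sd))
  env$noise_state <- res$state
  list(env = env, stimulus = base + res$value)
}

## Sample the successor of `current` (NULL/NA = episode start), honouring
## constrain_to. Returns list(state, restarted, infeasible).
sample_successor <- function(env, current, constrain_to = NULL) {
  restart <- function() {
    cands <- env$starts; w <- env$start_probs
    infeasible <- FALSE
    if (!is.null(constrain_to)) {
      keep <- cands %in% constrain_to
      if (any(keep)) { cands <- cands[keep]; w <- w[keep] / sum(w[keep]) }
      else infeasible <- TRUE
    }
    list(state = resample(cands, prob = w), restarted = TRUE, infeasible = infeasible)
  }
  if (is.null(current) || is.na(current)) return(restart())
  if (current == 0L) {  # transient novelty marker: resume the interrupted walk
    nxt <- env$transient_resume
    if (is.na(nxt)) return(restart())
    return(list(state = nxt, restarted = FALSE, infeasible = FALSE))
  }
  key <- as.character(current)
  if (key %in% names(env$novel_resume)) {
    nxt <- env$novel_resume[[key]]
    if (is.na(nxt)) return(restart())
    return(list(state = nxt, restarted = FALSE, infeasible = FALSE))
  }
  cands <- env$succ[[current]]
  if (length(cands) == 0L) return(restart())
  w <- env$succ_prob[[current]]
  if (!is.null(constrain_to)) {
    keep <- cands %in% constrain_to
    if (!any(keep)) return(restart())
    cands <- cands[keep]; w <- w[keep] / sum(w[keep])
  }
  list(state = resample(cands, prob = w), restarted = FALSE, infeasible = FALSE)
}

#' Advance the environment one step
#'
#' Samples the successor of `current` per the branch probabilities (terminal
#' states wrap around to a start state), optionally injects a brand-new
#' stimulus with probability `novelty_rate`, and emits a noisy stimulus.
#' When `constrain_to` is given — the hook the agent's constrain policy uses
#' — sampling is restricted to that state set (novelty injection is
#' suppressed); an empty constrained support is signalled via
#' `infeasible = TRUE` with an unconstrained restart as fallback.
#'
#' @param env an `env_model`.
#' @param current current state id, or `NULL` to (re)start an episode.
#' @param constrain_to optional integer vector of permitted states.
#' @return list with `env` (updated), `state` (id; `0` for a transient novel
#'   stimulus), `label`, `stimulus`, and flags `novel`, `restarted`,
#'   `infeasible`.
#' @export
step_environment <- function(env, current = NULL, constrain_to = NULL) {
  stopifnot(inherits(env, "env_model"))
  if (env$novelty_rate > 0 && is.null(constrain_to) &&
      stats::runif(1) < env$novelty_rate) {
    nxt <- sample_successor(env, current)
    proto_new <- draw_separated(env$proto, env$dim, max(env$min_sep, 1e-8),
                                nrow(env$proto) + 1L)
    if (env$novelty_persistent) {
      env$proto <- rbind(env$proto, proto_new)
      id <- nrow(env$proto)
      env$labels[id] <- paste0("novel", id - env$n_base)
      env$succ[[id]] <- integer(0); env$succ_prob[[id]] <- numeric(0)
      env$novel_resume[as.character(id)] <-
        if (nxt$restarted) NA_integer_ else nxt$state
      label <- env$labels[id]
    } else {
      env$transient_n <- env$transient_n + 1L
      env$transient_resume <- if (nxt$restarted) NA_integer_ else nxt$state
      id <- 0L
      label <- paste0("novelT", env$transient_n)
    }
    noise <- if (env$noise_sd > 0) {
      res <- with_rng_stream(env$noise_state, env$noise_seed,
                             stats::rnorm(env$dim, 0, env$noise_sd))
      env$noise_state <- res$state
      res$value
    } else rep(0, env$dim)
    return(list(env = env, state = id, label = label,
                stimulus = proto_new + noise, novel = TRUE,
                restarted = FALSE, infeasible = FALSE))
  }
  nxt <- sample_successor(env, current, constrain_to)
  em <- emit(env, nxt$state)
  list(env = em$env, state = nxt$state, label = em$env$labels[nxt$state],
       stimulus = em$stimulus, novel = FALSE,
       restarted = nxt$restarted, infeasible = nxt$infeasible)
}

#' Environment content hash
#'
#' md5 over prototypes (rounded), paths, weights and emission parameters;
#' used in run manifests so traces are attributable to an exact environment.
#'
#' @param env an `env_model`.
#' @return character md5 string.
#' @export
env_hash <- function(env) {
  object_md5(list(proto = round(env$proto, 10), paths = env$seq_paths,
                  w = round(env$path_w, 12), noise_sd = env$noise_sd,
                  novelty_rate = env$novelty_rate))
}
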