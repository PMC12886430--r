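## The stimuli-processing loop: perception (surprise vs T_so), nearest-
## neighbour classification, prediction (uncertainty vs T_a), then the
## behavior policy. The contrast between the learn and constrain policies is
## what operationalizes insistence on sameness; self-stimulation covers the
## sensory-deprivation regime.

#' Stochastic threshold model for sensory overload and anxiety
#'
#' The two thresholds are positive random variables: unknown, varying in
#' time, individual-specific. The default is lognormal (strictly positive
#' support) sampled independently per step; `"constant"` fixes them for
#' ablations and parameter-recovery tests.
#'
#' @param family `"lognormal"` or `"constant"`.
#' @param so,a parameter lists for the sensory-overload and anxiety
#'   thresholds: `list(meanlog=, sdlog=)` for lognormal, `list(value=)` for
#'   constant.
#' @param schedule `"per_step"` (resample every step, default) or
#'   `"per_episode"`.
#' @return an object of class `threshold_model`.
#' @export
threshold_model <- function(family = c("lognormal", "constant"),
                            so = list(meanlog = log(4), sdlog = 0.25),
                            a = list(meanlog = log(4), sdlog = 0.25),
                            schedule = c("per_step", "per_episode")) {
  family <- match.arg(family)
  schedule <- match.arg(schedule)
  if (family == "constant") {
    stopifnot(so$value > 0, a$value > 0)
  } else {
    stopifnot(is.numeric(so$meanlog), so$sdlog >= 0, is.numeric(a$meanlog), a$sdlog >= 0)
  }
  structure(list(family = family, so = so, a = a, schedule = schedule),
            class = "threshold_model")
}

sample_thresholds <- function(tm) {
  if (tm$family == "constant") return(c(so = tm$so$value, a = tm$a$value))
  c(so = stats::rlnorm(1, tm$so$meanlog, tm$so$sdlog),
    a = stats::rlnorm(1, tm$a$meanlog, tm$a$sdlog))
}

#' Agent configuration
#'
#' @param policy `"learn"` (store novel stimuli in memory), `"constrain"`
#'   (reject novel stimuli and redraw the environment from the known state
#'   set — the insistence-on-sameness policy), or `"passive"` (record only).
#' @param novelty_radius classification radius epsilon; `NULL` resolves to
#'   `0.45 * min_separation` of the environment at run time.
#' @param context_depth suffix-match depth for option sets; `Inf` (default)
#'   conditions on the whole current sequence, `1` is the Markov mode.
#' @param baseline_bits the agent's H(R) proxy for novel-stimulus fallbacks;
#'   `NULL` resolves to `log2(max(2, n environment states))`.
#' @param novelty_mass smoothing mass in (0,1) for realized surprisal.
#' @param event_rule which surprise measure is compared to T_so:
#'   `"realized_surprisal"` (per-stimulus -log2 p, default) or
#'   `"set_entropy"` (the option-set entropy).
#' @param selfstim_enabled allow self-generated known stimuli to displace
#'   high-surprisal ambient stimuli.
#' @param selfstim_floor_bits self-stimulation triggers when a novel ambient
#'   stimulus's surprisal exceeds `min(T_so, selfstim_floor_bits)`.
#' @param memory_weighting weighting for H(M) fallbacks, see
#'   [memory_entropy()].
#' @return an object of class `agent_config`.
#' @export
agent_config <- function(policy = c("learn", "constrain", "passive"),
                         novelty_radius = NULL, context_depth = Inf,
                         baseline_bits = NULL, novelty_mass = 2^-10,
                         event_rule = c("realized_surprisal", "set_entropy"),
                         selfstim_enabled = FALSE, selfstim_floor_bits = 1,
                         memory_weighting = c("counts", "uniform")) {
  policy <- match.arg(policy)
  event_rule <- match.arg(event_rule)
  if (!is.null(novelty_radius)) stopifnot(novelty_radius > 0)
  stopifnot(novelty_mass > 0, novelty_mass < 1, context_depth >= 1)
  structure(list(policy = policy, novelty_radius = novelty_radius,
                 context_depth = context_depth, baseline_bits = baseline_bits,
                 novelty_mass = novelty_mass, event_rule = event_rule,
                 selfstim_enabled = isTRUE(selfstim_enabled),
                 selfstim_floor_bits = selfstim_floor_bits,
                 memory_weighting = match.arg(memory_weighting)),
            class = "agent_config")
}

resolve_radius <- function(config, env) {
  if (!is.null(config$novelty_radius)) return(config$novelty_radius)
  if (env$min_sep <= 0)
    stopf("novelty_radius must be given explicitly for this environment")
  0.45 * env$min_sep
}

resolve_baseline <- function(config, env) {
  config$baseline_bits %||% log2(max(2, n_env_states(env)))
}

#' Environment states whose prototypes the memory already knows
#'
#' The state set the constrain policy restricts the environment to: states
#' whose prototype classifies as known (within the novelty radius of a
#' stored item).
#'
#' @param env an `env_model`.
#' @param g a [memory_graph()].
#' @param novelty_radius classification radius.
#' @return integer vector of state ids.
#' @export
known_env_states <- function(env, g, novelty_radius) {
  if (n_items(g) == 0L) return(integer(0))
  which(vapply(seq_len(nrow(env$proto)), function(s)
    !classify(g, env$proto[s, ], novelty_radius)$is_new, logical(1)))
}

## Measures of one processed stimulus against the current memory/context.
## Shared by run_episode and run_therapy so both log identical semantics.
measure_stimulus <- function(g, context, cls, config, baseline) {
  depth <- config$context_depth
  ## case split: a new stimulus is one the memorized context carries no
  ## information about (surprise = H(R) baseline); a known one is judged
  ## against the memorized option set (0 on a deterministic continuation).
  surprise <- if (isTRUE(cls$is_new)) baseline
  else perceptual_surprise(g, context, depth, baseline, 0)
  surprisal <- surprisal_of(g, context, cls, depth, baseline, config$novelty_mass)
  ctx2 <- if (!cls$is_new) c(context, cls$item_id) else context
  uncertainty <- predictive_uncertainty(g, cls, ctx2, depth, config$memory_weighting)
  disp <- if (length(context) > 0 && length(g$sequences) > 0)
    disappointment(g, context, cls, baseline, config$novelty_mass)$flag else FALSE
  list(surprise = surprise, surprisal = surprisal, uncertainty = uncertainty,
       so_measure = if (config$event_rule == "realized_surprisal") surprisal else surprise,
       disappointment = disp)
}

#' Run one simulated episode
#'
#' Executes the processing loop for `n_steps` stimuli: the environment
#' advances and emits, the agent (optionally) self-stimulates, measures
#' surprise and uncertainty against its memory, compares them to freshly
#' sampled thresholds, and acts per its policy. Deterministic given
#' `(config, env, thresholds, seed)`; sensory noise additionally depends
#' only on the environment's private noise seed.
#'
#' @param config an [agent_config()].
#' @param env an `env_model`.
#' @param n_steps number of steps (`>= 1`).
#' @param seed episode seed (drives trajectory, novelty and threshold
#'   draws).
#' @param thresholds a [threshold_model()].
#' @param init_memory optional starting [memory_graph()] (e.g. from
#'   [memorize_environment()]); default empty.
#' @return an `episode_trace`: a data frame with one row per step (columns
#'   `step`, `env_state`, `item_id`, `is_new`, `surprise`, `surprisal`,
#'   `uncertainty`, `t_so`, `t_a`, `overload`, `anxiety`, `disappointment`,
#'   `rejection`, `self_stim`, `restarted`, `novel_env`, `infeasible`) and
#'   attributes `config`, `thresholds`, `seed`, `env_hash`, `baseline_bits`,
#'   `final_memory`.
#' @export
run_episode <- function(config, env, n_steps, seed,
                        thresholds = threshold_model(), init_memory = NULL) {
  stopifnot(inherits(config, "agent_config"), inherits(env, "env_model"),
            inherits(thresholds, "threshold_model"))
  if (n_steps < 1) stopf("n_steps must be >= 1")
  eps <- resolve_radius(config, env)
  baseline <- resolve_baseline(config, env)
  hash <- env_hash(env)
  g <- init_memory %||% memory_graph(env$dim)
  if (g$dim != env$dim) stopf("memory dimension %d != environment dimension %d", g$dim, env$dim)
  g$open <- integer(0)
  context <- integer(0)
  cur <- NULL
  set.seed(seed)
  th <- sample_thresholds(thresholds)  # per-episode value; resampled below if per_step
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    prev_cur <- cur
    es <- step_environment(env, cur); env <- es$env
    restarted <- es$restarted
    if (restarted) { g <- close_sequence(g); context <- integer(0) }
    state <- es$state; label <- es$label; stim <- es$stimulus
    if (thresholds$schedule == "per_step") th <- sample_thresholds(thresholds)
    cls <- classify(g, stim, eps)
    self_stim <- FALSE
    if (config$selfstim_enabled && n_items(g) > 0 && cls$is_new) {
      amb <- surprisal_of(g, context, cls, config$context_depth, baseline,
                          config$novelty_mass)
      if (amb > min(th["so"], config$selfstim_floor_bits)) {
        stim <- g$prototypes[which.max(g$counts), ]  # most frequent known item
        cls <- classify(g, stim, eps)
        self_stim <- TRUE
        context <- integer(0)  # the stim routine restarts a known sequence
      }
    }
    rejection <- FALSE; infeasible <- FALSE
    if (config$policy == "constrain" && !self_stim) {
      known_cont <- !cls$is_new &&
        (length(context) == 0 ||
           as.character(cls$item_id) %in%
             names(continuation_counts(g, context, config$context_depth)))
      if (!known_cont) {
        rejection <- TRUE
        known <- known_env_states(env, g, eps)
        if (length(known) > 0) {
          es2 <- step_environment(env, prev_cur, constrain_to = known)
          env <- es2$env
          infeasible <- es2$infeasible
          if (es2$restarted) { context <- integer(0); restarted <- TRUE }
          state <- es2$state; label <- es2$label; stim <- es2$stimulus
          cls <- classify(g, stim, eps)
        }
      }
    }
    m <- measure_stimulus(g, context, cls, config, baseline)
    overload <- m$so_measure > th["so"]
    anxiety <- m$uncertainty > th["a"]
    if (config$policy == "learn") {
      prev <- if (length(g$open)) g$open[length(g$open)] else NA_integer_
      ins <- insert_observation(g, prev, stim, eps)
      g <- ins$graph
      item <- ins$item_id
      context <- g$open
    } else {
      item <- if (cls$is_new) NA_integer_ else cls$item_id
      context <- if (cls$is_new) integer(0) else c(context, cls$item_id)
    }
    cur <- state
    rows[[i]] <- data.frame(
      step = i, env_state = label,
      item_id = item, is_new = cls$is_new,
      surprise = m$surprise, surprisal = m$surprisal,
      uncertainty = m$uncertainty,
      t_so = unname(th["so"]), t_a = unname(th["a"]),
      overload = unname(overload), anxiety = unname(anxiety),
      disappointment = m$disappointment, rejection = rejection,
      self_stim = self_stim, restarted = restarted,
      novel_env = es$novel, infeasible = infeasible,
      stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("episode_trace", "data.frame")
  attr(trace, "config") <- config
  attr(trace, "thresholds") <- thresholds
  attr(trace, "seed") <- seed
  attr(trace, "env_hash") <- hash
  attr(trace, "baseline_bits") <- baseline
  attr(trace, "final_memory") <- close_sequence(g)
  trace
}

#' Final memory of an episode
#' @param trace an `episode_trace`.
#' @return the [memory_graph()] at episode end.
#' @export
final_memory <- function(trace) attr(trace, "final_memory")

#' Perfectly memorize an environment
#'
#' Builds the memory of an agent that has traversed every registered
#' environment sequence `times` times under noise-free emission: one item
#' per state, sequence registry matching the environment's sequence set.
#' The deterministic fixture behind "fully memorized" scenarios.
#'
#' @param env an `env_model`.
#' @param times traversals per sequence (drives counts).
#' @param novelty_radius classification radius; default `0.45 * min_sep`.
#' @return a [memory_graph()].
#' @export
memorize_environment <- function(env, times = 1, novelty_radius = NULL) {
  stopifnot(inherits(env, "env_model"))
  eps <- novelty_radius %||% (if (env$min_sep > 0) 0.45 * env$min_sep else
    stopf("novelty_radius needed for this environment"))
  g <- memory_graph(env$dim)
  for (rep in seq_len(times)) for (p in env$seq_paths) {
    prev <- NA_integer_
    for (s in p) {
      ins <- insert_observation(g, prev, env$proto[s, ], eps)
      g <- ins$graph
      prev <- ins$item_id
    }
    g <- close_sequence(g)
  }
  g
}

#' @export
print.episode_trace <- function(x, ...) {
  cat("<episode_trace: ", nrow(x), " steps, ",
      sum(x$overload), " overload / ", sum(x$anxiety), " anxiety / ",
      sum(x$rejection), " rejection events>\n", sep = "")
  invisible(x)
}

#' @export
summary.episode_trace <- function(object, ...) behavior_summary(object)

#' @export
plot.episode_trace <- function(x, ...) {
  graphics::plot(x$step, x$surprise, type = "l", col = "steelblue",
                 xlab = "step", ylab = "bits",
                 ylim = range(c(x$surprise, x$uncertainty, x$t_so, x$t_a)), ...)
  graphics::lines(x$step, x$uncertainty, col = "firebrick")
  graphics::lines(x$step, x$t_so, col = "steelblue", lty = 3)
  graphics::lines(x$step, x$t_a, col = "firebrick", lty = 3)
  graphics::legend("topright", legend = c("surprise", "uncertainty", "T_so", "T_a"),
                   col = c("steelblue", "firebrick", "steelblue", "firebrick"),
                   lty = c(1, 1, 3, 3), bty = "n")
  invisible(x)
}

#' Comfort-zone occupancy of a trace
#'
#' The fraction of steps where both the surprise and the uncertainty
#' measures stayed below their sampled thresholds (no overload, no anxiety).
#'
#' @param trace an `episode_trace`.
#' @return fraction in `[0, 1]`.
#' @export
comfort_zone_occupancy <- function(trace) {
  stopifnot(inherits(trace, "episode_trace"))
  if (nrow(trace) == 0L) stopf("empty trace")
  mean(!trace$overload & !trace$anxiety)
}

#' Per-episode behavior summary
#'
#' Event rates and information measures of a trace: overload, anxiety,
#' disappointment, rejection (the rigidity proxy) and self-stimulation
#' rates; route diversity (entropy of the visited-state distribution, the
#' vigilance/pedantry proxy); mean surprise and uncertainty; comfort-zone
#' occupancy; and the final entropy-distance estimate from the empirical
#' joint of (environment state, classified memory item), where novel
#' classifications share the label `"new"`.
#'
#' @param trace an `episode_trace`.
#' @return a one-row data frame of class `behavior_summary`.
#' @export
behavior_summary <- function(trace) {
  stopifnot(inherits(trace, "episode_trace"))
  if (nrow(trace) == 0L) stopf("empty trace")
  m_label <- ifelse(trace$is_new, "new", paste0("m", trace$item_id))
  j <- empirical_joint(trace$env_state, m_label)
  out <- data.frame(
    n_steps = nrow(trace),
    overload_rate = mean(trace$overload),
    anxiety_rate = mean(trace$anxiety),
    disappointment_rate = mean(trace$disappointment),
    rejection_rate = mean(trace$rejection),
    selfstim_rate = mean(trace$self_stim),
    route_diversity = shannon_bits(as.numeric(table(trace$env_state)) / nrow(trace)),
    mean_surprise = mean(trace$surprise),
    mean_uncertainty = mean(trace$uncertainty),
    comfort_zone = comfort_zone_occupancy(trace),
    d_h = entropy_distance(j))
  class(out) <- c("behavior_summary", "data.frame")
  out
}

#' Digital-twin comparison of two agent configurations
#'
#' Runs matched-seed episode pairs of two configurations in the same
#' environment and tabulates per-metric means, mean differences and a paired
#' sign test — the Turing-test-like surface on which an expert can compare
#' simulated behavior profiles.
#'
#' @param config_a,config_b two [agent_config()]s.
#' @param env an `env_model`.
#' @param n_steps steps per episode.
#' @param n_reps number of matched seed pairs (`>= 1`).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param thresholds a [threshold_model()].
#' @param init_memory optional shared starting memory.
#' @return a data frame of class `twin_comparison` with one row per metric:
#'   `mean_a`, `mean_b`, `mean_diff` (a - b), `n_a_lower`, `p_sign`
#'   (two-sided exact sign test over non-tied pairs).
#' @export
twin_compare <- function(config_a, config_b, env, n_steps, n_reps, seed,
                         thresholds = threshold_model(), init_memory = NULL) {
  stopifnot(n_reps >= 1)
  run_one <- function(cfg, s)
    behavior_summary(run_episode(cfg, env, n_steps, s, thresholds, init_memory))
  sa <- do.call(rbind, lapply(seq_len(n_reps), function(r) run_one(config_a, seed + r)))
  sb <- do.call(rbind, lapply(seq_len(n_reps), function(r) run_one(config_b, seed + r)))
  metrics <- setdiff(names(sa), "n_steps")
  out <- do.call(rbind, lapply(metrics, function(mt) {
    d <- sa[[mt]] - sb[[mt]]
    nz <- d[d != 0]
    p <- if (length(nz) == 0) 1 else
      stats::binom.test(sum(nz > 0), length(nz))$p.value
    data.frame(metric = mt, mean_a = mean(sa[[mt]]), mean_b = mean(sb[[mt]]),
               mean_diff = mean(d), n_a_lower = sum(d < 0), p_sign = p,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_reps") <- n_reps
  attr(out, "per_rep") <- list(a = sa, b = sb)
  class(out) <- c("twin_comparison", "data.frame")
  out
}

#' @export
print.twin_comparison <- function(x, ...) {
  cat("Twin comparison over", attr(x, "n_reps"), "matched seed pairs\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
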