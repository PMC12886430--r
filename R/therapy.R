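## The curriculum scheduler: choose what to present next so as to maximize
## the mutual information I(R;M) while keeping predicted surprise and
## uncertainty below estimated thresholds. Since D_H(R,M) = H(R,M) - I(R;M),
## raising I at a given joint lowers the entropy distance the agent lives
## with.

#' Estimate the overload / anxiety thresholds from traces
#'
#' The thresholds are never observed directly; each step only brackets them:
#' an event step says the sampled threshold was below the logged measure
#' (left-censored), a quiet step says it was above (right-censored). The
#' per-channel threshold distribution is fitted by the Turnbull
#' interval-censored NPMLE (via \pkg{survival}) and the conservative
#' `q`-quantile is read off. A channel with no events at all yields only
#' lower bounds; the estimate then falls back to the maximum observed
#' measure plus a margin and is flagged `censored_only`.
#'
#' @param traces a list of `episode_trace` objects (or a single one).
#' @param q quantile in (0,1) at which thresholds are estimated (default
#'   0.1, conservative).
#' @param margin bits added to the fallback estimate in the no-event case.
#' @return an object of class `threshold_estimate`: `t_so`, `t_a`, `q`,
#'   event/step counts, `censored_only` flags.
#' @export
estimate_thresholds <- function(traces, q = 0.1, margin = 0.5) {
  if (inherits(traces, "episode_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, q > 0, q < 1)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    cfg <- attr(tr, "config")
    data.frame(
      so_measure = if (cfg$event_rule == "realized_surprisal") tr$surprisal else tr$surprise,
      overload = tr$overload, a_measure = tr$uncertainty, anxiety = tr$anxiety)
  }))
  fit_channel <- function(measure, event) {
    n_ev <- sum(event)
    if (n_ev == 0L)
      return(list(est = max(measure) + margin, censored_only = TRUE))
    if (n_ev == length(event))
      return(list(est = max(min(measure) - margin, min(measure) * 0.5), censored_only = TRUE))
    left <- ifelse(event, NA_real_, measure)
    right <- ifelse(event, measure, NA_real_)
    fit <- survival::survfit(survival::Surv(left, right, type = "interval2") ~ 1)
    est <- unname(stats::quantile(fit, probs = q, conf.int = FALSE))
    if (is.list(est)) est <- est$quantile
    if (is.na(est)) est <- min(measure[event])  # q below the fitted support
    list(est = est, censored_only = FALSE)
  }
  so <- fit_channel(rows$so_measure, rows$overload)
  a <- fit_channel(rows$a_measure, rows$anxiety)
  if (so$censored_only || a$censored_only)
    warning("a channel had events on only one side of its threshold; returning a bound-based estimate")
  structure(list(t_so = so$est, t_a = a$est, q = q,
                 n = c(so_events = sum(rows$overload), a_events = sum(rows$anxiety),
                       steps = nrow(rows)),
                 censored_only = c(so = so$censored_only, a = a$censored_only)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate (q = %.2f): T_so ~ %.3f bits, T_a ~ %.3f bits; %d/%d/%d overload/anxiety/steps>\n",
              x$q, x$t_so, x$t_a, x$n["so_events"], x$n["a_events"], x$n["steps"]))
  invisible(x)
}

## Noise-free scripted presentation of one candidate sequence to a
## (copied) memory; returns the per-step measures and the updated memory.
present_candidate <- function(g, env, path, config, baseline, eps, learn = TRUE) {
  context <- integer(0)
  g$open <- integer(0)
  max_so <- 0; max_unc <- 0
  for (s in path) {
    stim <- env$proto[s, ]
    cls <- classify(g, stim, eps)
    m <- measure_stimulus(g, context, cls, config, baseline)
    max_so <- max(max_so, m$so_measure)
    max_unc <- max(max_unc, m$uncertainty)
    if (learn) {
      prev <- if (length(g$open)) g$open[length(g$open)] else NA_integer_
      ins <- insert_observation(g, prev, stim, eps)
      g <- ins$graph
      context <- g$open
    } else {
      context <- if (cls$is_new) integer(0) else c(context, cls$item_id)
    }
  }
  if (learn) g <- close_sequence(g)
  list(max_so = max_so, max_unc = max_unc, graph = g)
}

#' Estimate I(R;M) for a memory in an environment
#'
#' Plug-in mutual information of the empirical joint of (environment state,
#' classified memory item) over seeded noisy traversals of all registered
#' environment sequences; novel classifications share the label `"new"`.
#'
#' @param env an `env_model`.
#' @param g a [memory_graph()].
#' @param config an [agent_config()] (novelty radius resolution).
#' @param n_rollouts traversals of the sequence set.
#' @return bits.
#' @export
mi_estimate <- function(env, g, config = agent_config("passive"), n_rollouts = 2) {
  eps <- resolve_radius(config, env)
  r_lab <- character(0); m_lab <- character(0)
  for (k in seq_len(n_rollouts)) for (p in env$seq_paths) for (s in p) {
    em <- emit(env, s); env <- em$env
    cls <- classify(g, em$stimulus, eps)
    r_lab <- c(r_lab, env$labels[s])
    m_lab <- c(m_lab, if (cls$is_new) "new" else paste0("m", cls$item_id))
  }
  mutual_information(empirical_joint(r_lab, m_lab))
}

#' Predicted mutual-information gain of learning a candidate
#'
#' Estimates I(R;M) before vs after hypothetically learning the candidate
#' sequence on a copy of the memory; the same seeded stimulus rollouts are
#' classified under both memories, so the returned difference isolates the
#' effect of the candidate.
#'
#' @param g a [memory_graph()].
#' @param env an `env_model`.
#' @param candidate integer vector of environment state ids (a complete
#'   registered sequence).
#' @param config an [agent_config()].
#' @param n_rollouts rollouts used for the estimate.
#' @param seed seed for the rollout stream.
#' @return bits (difference; approximately non-negative).
#' @export
mi_gain <- function(g, env, candidate, config = agent_config("learn"),
                    n_rollouts = 2, seed = 1) {
  eps <- resolve_radius(config, env)
  baseline <- resolve_baseline(config, env)
  g2 <- present_candidate(g, env, candidate, config, baseline, eps, learn = TRUE)$graph
  set.seed(seed)
  stims <- list(); r_lab <- character(0)
  for (k in seq_len(n_rollouts)) for (p in env$seq_paths) for (s in p) {
    em <- emit(env, s); env <- em$env
    stims[[length(stims) + 1L]] <- em$stimulus
    r_lab <- c(r_lab, env$labels[s])
  }
  lab <- function(gg) vapply(stims, function(x) {
    cls <- classify(gg, x, eps)
    if (cls$is_new) "new" else paste0("m", cls$item_id)
  }, character(1))
  mutual_information(empirical_joint(r_lab, lab(g2))) -
    mutual_information(empirical_joint(r_lab, lab(g)))
}

#' Guideline settings for the therapy planner
#'
#' @param nu_max optional cap on branch alternatives; when set, the planner
#'   first applies [transform_limit_options()].
#' @param gain_floor stop when the best feasible predicted gain falls below
#'   this (bits).
#' @param n_rollouts rollouts per MI-gain estimate.
#' @param allow_branch_to_start let the planner apply
#'   [transform_branch_to_start()] when no candidate is feasible and the
#'   transform unlocks one.
#' @param recommend_amulets record an amulet-transform recommendation when
#'   infeasibility persists (the transform changes the stimulus encoding, so
#'   it is reported rather than silently applied).
#' @return a list of class `therapy_guidelines`.
#' @export
therapy_guidelines <- function(nu_max = NULL, gain_floor = 0.02, n_rollouts = 2,
                               allow_branch_to_start = FALSE,
                               recommend_amulets = TRUE) {
  structure(list(nu_max = nu_max, gain_floor = gain_floor,
                 n_rollouts = n_rollouts,
                 allow_branch_to_start = isTRUE(allow_branch_to_start),
                 recommend_amulets = isTRUE(recommend_amulets)),
            class = "therapy_guidelines")
}

#' Plan a therapy curriculum
#'
#' Greedy solution of the constrained MI-maximization problem over a finite
#' candidate set: at each round, among candidates whose predicted per-step
#' surprise and uncertainty (max over the scripted presentation against the
#' current simulated memory) stay below the threshold estimates, schedule
#' the one with the largest predicted MI gain; learning the pick updates the
#' simulated memory. Stops when no candidate is feasible ("no safe entry
#' point" if at round one), when gains fall below the floor, or when
#' candidates are exhausted. Candidates are complete environment sequences —
#' never fragments.
#'
#' @param g the initial [memory_graph()].
#' @param env an `env_model`.
#' @param thresholds a `threshold_estimate` (from
#'   [estimate_thresholds()]).
#' @param candidates list of state-id paths; default: all registered
#'   environment sequences.
#' @param config an [agent_config()] (measure semantics).
#' @param guidelines a [therapy_guidelines()].
#' @param seed seed for gain-estimation rollouts.
#' @return a data frame of class `therapy_plan` (columns `round`,
#'   `candidate`, `predicted_surprise`, `predicted_uncertainty`,
#'   `predicted_gain`) with attributes `stopping_reason`, `thresholds`,
#'   `candidates`, `init_memory`, `env`, `transforms_applied`,
#'   `recommended_transforms`.
#' @export
plan_therapy <- function(g, env, thresholds, candidates = NULL,
                         config = agent_config("learn"),
                         guidelines = therapy_guidelines(), seed = 1) {
  stopifnot(inherits(thresholds, "threshold_estimate"))
  transforms <- character(0); recommended <- character(0)
  if (!is.null(guidelines$nu_max)) {
    env <- transform_limit_options(env, guidelines$nu_max)
    transforms <- c(transforms, sprintf("limit_options(%d)", guidelines$nu_max))
    candidates <- NULL  # pruned sequence set replaces any stale candidate list
  }
  candidates <- candidates %||% env$seq_paths
  if (length(candidates) == 0) stopf("no candidates")
  eps <- resolve_radius(config, env)
  baseline <- resolve_baseline(config, env)
  init_memory <- g
  remaining <- seq_along(candidates)
  rows <- list(); round <- 0L
  stopping <- "exhausted"
  repeat {
    if (length(remaining) == 0) { stopping <- "exhausted"; break }
    round <- round + 1L
    pred <- lapply(remaining, function(i)
      present_candidate(g, env, candidates[[i]], config, baseline, eps, learn = TRUE))
    feas <- vapply(pred, function(p)
      p$max_so < thresholds$t_so && p$max_unc < thresholds$t_a, logical(1))
    if (!any(feas)) {
      if (guidelines$allow_branch_to_start && !"branch_to_start" %in% transforms) {
        env2 <- transform_branch_to_start(env)
        pred2 <- lapply(remaining, function(i)
          present_candidate(g, env2, env2$seq_paths[[i]], config, baseline, eps, learn = TRUE))
        feas2 <- vapply(pred2, function(p)
          p$max_so < thresholds$t_so && p$max_unc < thresholds$t_a, logical(1))
        if (any(feas2)) {
          env <- env2; candidates <- env2$seq_paths
          transforms <- c(transforms, "branch_to_start")
          pred <- pred2; feas <- feas2
        }
      }
      if (!any(feas)) {
        if (guidelines$recommend_amulets) recommended <- c(recommended, "amulets")
        stopping <- if (round == 1L) "no safe entry point" else "no feasible candidate"
        break
      }
    }
    gains <- rep(-Inf, length(remaining))
    gains[feas] <- vapply(which(feas), function(k)
      mi_gain(g, env, candidates[[remaining[k]]], config,
              guidelines$n_rollouts, seed + 97L * round + remaining[k]),
      numeric(1))
    best <- which.max(gains)
    if (gains[best] < guidelines$gain_floor) { stopping <- "no positive gain"; break }
    i <- remaining[best]
    rows[[round]] <- data.frame(
      round = round, candidate = i,
      predicted_surprise = pred[[best]]$max_so,
      predicted_uncertainty = pred[[best]]$max_unc,
      predicted_gain = gains[best])
    g <- pred[[best]]$graph
    remaining <- remaining[-best]
  }
  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(round = integer(0), candidate = integer(0),
               predicted_surprise = numeric(0), predicted_uncertainty = numeric(0),
               predicted_gain = numeric(0))
  class(plan) <- c("therapy_plan", "data.frame")
  attr(plan, "stopping_reason") <- stopping
  attr(plan, "thresholds") <- thresholds
  attr(plan, "candidates") <- candidates
  attr(plan, "init_memory") <- init_memory
  attr(plan, "env") <- env
  attr(plan, "transforms_applied") <- transforms
  attr(plan, "recommended_transforms") <- unique(recommended)
  plan
}

#' @export
print.therapy_plan <- function(x, ...) {
  cat("<therapy_plan: ", nrow(x), " scheduled candidates; stop: ",
      attr(x, "stopping_reason"), ">\n", sep = "")
  if (nrow(x)) {
    df <- as.data.frame(x); df[-(1:2)] <- lapply(df[-(1:2)], function(v) signif(v, 4))
    print(df, row.names = FALSE)
  }
  if (length(attr(x, "transforms_applied")))
    cat("transforms applied:", paste(attr(x, "transforms_applied"), collapse = ", "), "\n")
  if (length(attr(x, "recommended_transforms")))
    cat("recommended:", paste(attr(x, "recommended_transforms"), collapse = ", "), "\n")
  invisible(x)
}

#' Execute a therapy plan
#'
#' Presents the scheduled sequences, in order, to a learn-policy agent under
#' noisy emission and stochastic thresholds; records the per-step trace, the
#' MI estimate after each candidate, and the realized constraint-violation
#' (overload or anxiety) rate.
#'
#' @param config an [agent_config()] (`learn` policy enforced).
#' @param env an `env_model`; defaults to the plan's (possibly transformed)
#'   environment.
#' @param plan a [plan_therapy()] result (non-empty).
#' @param seed episode seed.
#' @param thresholds the true [threshold_model()] generating per-step
#'   thresholds.
#' @param n_rollouts rollouts per MI estimate.
#' @return list of class `therapy_run`: `trace` (an `episode_trace`),
#'   `mi_trajectory` (data frame `candidate`, `mi_bits`), `event_rate`.
#' @export
run_therapy <- function(config, env = NULL, plan, seed,
                        thresholds = threshold_model(), n_rollouts = 2) {
  stopifnot(inherits(plan, "therapy_plan"))
  if (nrow(plan) == 0) stopf("empty therapy plan")
  env <- env %||% attr(plan, "env")
  config$policy <- "learn"
  eps <- resolve_radius(config, env)
  baseline <- resolve_baseline(config, env)
  g <- attr(plan, "init_memory") %||% memory_graph(env$dim)
  g$open <- integer(0)
  candidates <- attr(plan, "candidates")
  set.seed(seed)
  th <- sample_thresholds(thresholds)
  rows <- list(); mi_rows <- list(); step <- 0L
  for (k in seq_len(nrow(plan))) {
    path <- candidates[[plan$candidate[k]]]
    context <- integer(0); g$open <- integer(0)
    for (s in path) {
      step <- step + 1L
      em <- emit(env, s); env <- em$env
      if (thresholds$schedule == "per_step") th <- sample_thresholds(thresholds)
      cls <- classify(g, em$stimulus, eps)
      m <- measure_stimulus(g, context, cls, config, baseline)
      prev <- if (length(g$open)) g$open[length(g$open)] else NA_integer_
      ins <- insert_observation(g, prev, em$stimulus, eps)
      g <- ins$graph; context <- g$open
      rows[[step]] <- data.frame(
        step = step, env_state = env$labels[s], item_id = ins$item_id,
        is_new = cls$is_new, surprise = m$surprise, surprisal = m$surprisal,
        uncertainty = m$uncertainty, t_so = unname(th["so"]), t_a = unname(th["a"]),
        overload = unname(m$so_measure > th["so"]),
        anxiety = unname(m$uncertainty > th["a"]),
        disappointment = m$disappointment, rejection = FALSE,
        self_stim = FALSE, restarted = s == path[1], novel_env = FALSE,
        infeasible = FALSE, stringsAsFactors = FALSE)
    }
    g <- close_sequence(g)
    mi_rows[[k]] <- data.frame(candidate = plan$candidate[k],
                               mi_bits = mi_estimate(env, g, config, n_rollouts))
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("episode_trace", "data.frame")
  attr(trace, "config") <- config
  attr(trace, "thresholds") <- thresholds
  attr(trace, "seed") <- seed
  attr(trace, "env_hash") <- env_hash(env)
  attr(trace, "baseline_bits") <- baseline
  attr(trace, "final_memory") <- g
  structure(list(trace = trace,
                 mi_trajectory = do.call(rbind, mi_rows),
                 event_rate = mean(trace$overload | trace$anxiety)),
            class = "therapy_run")
}

#' @export
print.therapy_run <- function(x, ...) {
  cat("<therapy_run: ", nrow(x$trace), " steps, event rate ",
      signif(x$event_rate, 3), ">\n", sep = "")
  print(x$mi_trajectory, row.names = FALSE)
  invisible(x)
}
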