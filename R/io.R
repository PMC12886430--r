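## Configuration, presets, trace/report writers and the command-line entry
## points binding the modules into reproducible runs. Every run writes a
## manifest (config hash, env hash, seeds, version) from which its outputs
## are reproducible.

PRESET_NAMES <- c("chain", "branching", "nonstationary", "deprivation")

#' Preset environments
#'
#' Shipped study environments: `"chain"` (one deterministic 8-state
#' sequence), `"branching"` (two trunks with a 2-way branch after position
#' 3), `"nonstationary"` (branching plus 5% novelty injection) and
#' `"deprivation"` (endogenous noise only).
#'
#' @param name one of `"chain"`, `"branching"`, `"nonstationary"`,
#'   `"deprivation"`.
#' @param seed structural seed.
#' @return an `env_model`.
#' @export
preset_environment <- function(name, seed = 1) {
  name <- match.arg(name, PRESET_NAMES)
  switch(name,
    chain = generate_environment(env_spec(
      n_sequences = 1, seq_length = 8, dim = 8, min_separation = 1,
      noise_sd = 0.02, seed = seed)),
    branching = generate_environment(env_spec(
      n_sequences = 2, seq_length = 6, branch_positions = 3, branch_arity = 2,
      dim = 8, min_separation = 1, noise_sd = 0.02, seed = seed)),
    nonstationary = generate_environment(env_spec(
      n_sequences = 2, seq_length = 6, branch_positions = 3, branch_arity = 2,
      dim = 8, min_separation = 1, noise_sd = 0.02, novelty_rate = 0.05,
      seed = seed)),
    deprivation = deprivation_environment(dim = 8, noise_sd_endo = 1, seed = seed))
}

## ---- run configuration ----------------------------------------------------

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stopf("unknown %s key(s): %s", where, paste(extra, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON mappings with top-level keys `env`
#' (preset name or [env_spec()] fields), `agent` ([agent_config()] fields),
#' `thresholds` ([threshold_model()] fields), `therapy`, `twin`, `n_steps`,
#' `n_reps`, `seed` and `out_dir`. Unknown keys anywhere are rejected before
#' any computation.
#'
#' @param path file path to a `.yaml`/`.yml`/`.json` config, or a list.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  check_keys(cfg, c("env", "agent", "thresholds", "therapy", "twin",
                    "n_steps", "n_reps", "seed", "out_dir"), "config")
  if (is.null(cfg$env)) stopf("config needs an 'env' entry")
  if (is.list(cfg$env))
    check_keys(cfg$env, c("n_sequences", "seq_length", "branch_positions",
                          "branch_arity", "branch_probs", "dim", "min_separation",
                          "noise_sd", "novelty_rate", "seed", "novelty_persistent"),
               "env")
  else if (!cfg$env %in% PRESET_NAMES)
    stopf("unknown env preset '%s'", cfg$env)
  if (!is.null(cfg$agent))
    check_keys(cfg$agent, c("policy", "novelty_radius", "context_depth",
                            "baseline_bits", "novelty_mass", "event_rule",
                            "selfstim_enabled", "selfstim_floor_bits",
                            "memory_weighting"), "agent")
  if (!is.null(cfg$thresholds))
    check_keys(cfg$thresholds, c("family", "so", "a", "schedule"), "thresholds")
  if (!is.null(cfg$therapy)) {
    check_keys(cfg$therapy, c("q", "gain_floor", "nu_max", "n_calibration_steps",
                              "n_rollouts", "allow_branch_to_start"), "therapy")
    q <- cfg$therapy$q %||% 0.1
    if (q <= 0 || q >= 1) stopf("therapy q must be in (0,1)")
  }
  if (!is.null(cfg$twin))
    check_keys(cfg$twin, c("policy_a", "policy_b", "pretrain"), "twin")
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$n_steps <- as.integer(cfg$n_steps %||% 200)
  cfg$n_reps <- as.integer(cfg$n_reps %||% 5)
  if (cfg$n_steps < 1) stopf("n_steps must be >= 1")
  if (cfg$n_reps < 1) stopf("n_reps must be >= 1")
  structure(cfg, class = "run_config")
}

config_env <- function(cfg) {
  if (is.list(cfg$env)) generate_environment(do.call(env_spec, cfg$env))
  else preset_environment(cfg$env, cfg$seed)
}

config_agent <- function(cfg, policy = NULL) {
  args <- cfg$agent %||% list()
  if (!is.null(policy)) args$policy <- policy
  if (!is.null(args$context_depth) && identical(args$context_depth, "full"))
    args$context_depth <- Inf
  do.call(agent_config, args)
}

config_thresholds <- function(cfg) {
  do.call(threshold_model, cfg$thresholds %||% list())
}

## ---- writers --------------------------------------------------------------

#' Write / read traces and summaries
#'
#' Episode traces are written as CSV (one row per step) and JSONL (one JSON
#' record per step); summaries and comparison tables as CSV. All writers are
#' deterministic: identical inputs give byte-identical files.
#'
#' @param trace an `episode_trace` (or plain data frame).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_trace_jsonl <- function(trace, path) {
  df <- as.data.frame(trace)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, ]), digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_manifest <- function(path, cfg, env, extra = list()) {
  manifest <- c(list(
    package = "entrosim",
    version = as.character(utils::packageVersion("entrosim")),
    config = unclass(cfg),
    config_hash = object_md5(unclass(cfg)),
    env_hash = env_hash(env),
    seed = cfg$seed), extra)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"), path)
  invisible(path)
}

## ---- command-line entry points --------------------------------------------

#' Run a simulation / therapy / twin experiment from a config
#'
#' The programmatic core of the shell interface (see
#' `system.file("cli/entrosim.R", package = "entrosim")`).
#' `cli_simulate()` runs one episode and writes the trace (CSV + JSONL),
#' behavior summary CSV, final memory (JSON + GraphML) and a run manifest.
#' `cli_therapy()` runs a calibration episode, estimates thresholds, plans
#' and executes the curriculum, and writes the plan JSON, MI-trajectory CSV
#' and trace. `cli_twin()` runs the matched-seed policy comparison and
#' writes the comparison table.
#'
#' @param config path to a YAML/JSON config, or a list (see
#'   [run_config()]).
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return invisibly, a named list of written file paths.
#' @export
cli_simulate <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  out <- out_dir %||% cfg$out_dir %||% stopf("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  env <- config_env(cfg)
  trace <- run_episode(config_agent(cfg), env, cfg$n_steps, cfg$seed,
                       config_thresholds(cfg))
  paths <- list(
    trace_csv = file.path(out, "trace.csv"),
    trace_jsonl = file.path(out, "trace.jsonl"),
    summary_csv = file.path(out, "summary.csv"),
    memory_json = file.path(out, "memory.json"),
    memory_graphml = file.path(out, "memory.graphml"),
    manifest = file.path(out, "manifest.json"))
  write_trace_csv(trace, paths$trace_csv)
  write_trace_jsonl(trace, paths$trace_jsonl)
  utils::write.csv(as.data.frame(behavior_summary(trace)), paths$summary_csv,
                   row.names = FALSE)
  export_memory(final_memory(trace), paths$memory_json, "json")
  export_memory(final_memory(trace), paths$memory_graphml, "graphml")
  write_manifest(paths$manifest, cfg, env,
                 list(outputs = vapply(paths, basename, character(1))))
  invisible(paths)
}

#' @rdname cli_simulate
#' @export
cli_therapy <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  out <- out_dir %||% cfg$out_dir %||% stopf("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  env <- config_env(cfg)
  if (length(env$seq_paths) == 0) stopf("no candidates")
  tcfg <- cfg$therapy %||% list()
  tm <- config_thresholds(cfg)
  ## the planner's constraint is the conditional-entropy level itself, so
  ## therapy runs default to the set-entropy event rule unless overridden
  if (is.null(cfg$agent$event_rule)) cfg$agent$event_rule <- "set_entropy"
  agent <- config_agent(cfg, policy = "learn")
  calib <- run_episode(agent, env, tcfg$n_calibration_steps %||% 200,
                       cfg$seed, tm)
  est <- estimate_thresholds(calib, q = tcfg$q %||% 0.1)
  plan <- plan_therapy(memory_graph(env$dim), env, est, config = agent,
                       guidelines = therapy_guidelines(
                         nu_max = tcfg$nu_max,
                         gain_floor = tcfg$gain_floor %||% 0.02,
                         n_rollouts = tcfg$n_rollouts %||% 2,
                         allow_branch_to_start = isTRUE(tcfg$allow_branch_to_start)),
                       seed = cfg$seed)
  paths <- list(plan_json = file.path(out, "plan.json"),
                mi_csv = file.path(out, "mi_trajectory.csv"),
                trace_csv = file.path(out, "therapy_trace.csv"),
                manifest = file.path(out, "manifest.json"))
  plan_doc <- list(schedule = as.data.frame(plan),
                   stopping_reason = attr(plan, "stopping_reason"),
                   thresholds = unclass(attr(plan, "thresholds")),
                   transforms_applied = attr(plan, "transforms_applied"),
                   recommended_transforms = attr(plan, "recommended_transforms"))
  writeLines(jsonlite::toJSON(plan_doc, digits = NA, auto_unbox = TRUE, pretty = TRUE),
             paths$plan_json)
  if (nrow(plan) > 0) {
    res <- run_therapy(agent, attr(plan, "env"), plan, cfg$seed + 1L, tm)
    utils::write.csv(res$mi_trajectory, paths$mi_csv, row.names = FALSE)
    write_trace_csv(res$trace, paths$trace_csv)
  }
  write_manifest(paths$manifest, cfg, env, list(stopping = attr(plan, "stopping_reason")))
  invisible(paths)
}

#' @rdname cli_simulate
#' @export
cli_twin <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  out <- out_dir %||% cfg$out_dir %||% stopf("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  env <- config_env(cfg)
  twin <- cfg$twin %||% list()
  ca <- config_agent(cfg, policy = twin$policy_a %||% "constrain")
  cb <- config_agent(cfg, policy = twin$policy_b %||% "passive")
  init <- if (isTRUE(twin$pretrain %||% TRUE)) memorize_environment(env) else NULL
  cmp <- twin_compare(ca, cb, env, cfg$n_steps, cfg$n_reps, cfg$seed,
                      config_thresholds(cfg), init)
  paths <- list(comparison_csv = file.path(out, "comparison.csv"),
                manifest = file.path(out, "manifest.json"))
  utils::write.csv(as.data.frame(cmp), paths$comparison_csv, row.names = FALSE)
  write_manifest(paths$manifest, cfg, env,
                 list(policies = c(ca$policy, cb$policy)))
  invisible(paths)
}
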