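# Environment generators: topology, determinism, separation, emission
# statistics, novelty injection, constrained stepping, deprivation and the
# guideline transforms.

min_pairwise_dist <- function(P) {
  if (nrow(P) < 2) return(Inf)
  min(stats::dist(P))
}

test_that("environment specs are validated before generation", {
  expect_error(env_spec(branch_positions = 2, branch_arity = 1), "branch_arity")
  expect_error(env_spec(seq_length = 5, branch_positions = 5), "branch_positions")
  expect_error(env_spec(branch_positions = 2, branch_probs = c(0.9, 0.9)),
               "distribution")
  expect_error(env_spec(min_separation = 0), "min_separation")
  expect_error(env_spec(novelty_rate = 1.5), "novelty_rate")
})

test_that("generation is deterministic and respects topology and separation", {
  spec <- env_spec(n_sequences = 1, seq_length = 6, seed = 5)
  env <- generate_environment(spec)
  expect_equal(length(env$seq_paths), 1L)
  expect_equal(n_env_states(env), 6L)
  expect_true(all(lengths(env$succ) <= 1))  # pure chain
  expect_identical(generate_environment(spec)$proto, env$proto)

  spec3 <- env_spec(n_sequences = 1, seq_length = 5, branch_positions = 2,
                    branch_arity = 3, dim = 10, seed = 6)
  env3 <- generate_environment(spec3)
  expect_equal(length(env3$seq_paths), 3L)
  expect_equal(sum(lengths(env3$succ) == 3), 1L)  # exactly one 3-way branch state
  expect_gte(min_pairwise_dist(env3$proto), env3$min_sep)

  # the caller's RNG is not consumed by generation
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_environment(spec)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("emission adds isotropic Gaussian noise around the prototype", {
  env <- generate_environment(env_spec(seq_length = 3, noise_sd = 0, seed = 2))
  expect_identical(emit(env, 1)$stimulus, env$proto[1, ])
  env2 <- generate_environment(env_spec(seq_length = 3, noise_sd = 0.3, seed = 2))
  # reproducible given the noise seed
  s1 <- emit(env2, 1)$stimulus
  s2 <- emit(set_noise_seed(env2, env2$noise_seed), 1)$stimulus
  expect_identical(s1, s2)
  # CLT: the mean of 1000 emissions is within 4 sd / sqrt(n) per coordinate
  acc <- matrix(0, 1000, env2$dim)
  e <- env2
  for (i in 1:1000) { em <- emit(e, 2); e <- em$env; acc[i, ] <- em$stimulus }
  expect_true(all(abs(colMeans(acc) - env2$proto[2, ]) < 4 * 0.3 / sqrt(1000)))
})

test_that("stepping follows the chain, samples branches at their probabilities, and wraps", {
  env <- generate_environment(env_spec(seq_length = 4, noise_sd = 0, seed = 3))
  p <- env$seq_paths[[1]]
  set.seed(1)
  es <- step_environment(env, p[1])
  expect_equal(es$state, p[2])
  expect_false(es$restarted)
  # terminal state wraps to a start
  es2 <- step_environment(env, p[4])
  expect_true(es2$restarted)
  expect_equal(es2$state, p[1])

  envb <- generate_environment(env_spec(seq_length = 4, branch_positions = 2,
                                        branch_arity = 2, dim = 8, seed = 4))
  branch_state <- which(lengths(envb$succ) == 2)
  kids <- envb$succ[[branch_state]]
  set.seed(42)
  picks <- replicate(10000, step_environment(envb, branch_state)$state)
  expect_equal(mean(picks == kids[1]), 0.5, tolerance = 0.02)
})

test_that("novelty injection emits separated prototypes, persistent or transient", {
  env <- generate_environment(env_spec(seq_length = 3, novelty_rate = 1,
                                       noise_sd = 0, seed = 7))
  p <- env$seq_paths[[1]]
  set.seed(8)
  es <- step_environment(env, p[1])
  expect_true(es$novel)
  expect_equal(n_env_states(es$env), 4L)  # persisted as a new state
  expect_gte(min_pairwise_dist(es$env$proto), env$min_sep)
  # resuming from the novel state continues the interrupted walk
  # (constraining suppresses further injection at novelty_rate = 1)
  es2 <- step_environment(es$env, es$state,
                          constrain_to = seq_len(n_env_states(es$env)))
  expect_equal(es2$state, p[2])
  expect_false(es2$novel || es2$restarted)

  envt <- generate_environment(env_spec(seq_length = 3, novelty_rate = 1,
                                        noise_sd = 0, seed = 7,
                                        novelty_persistent = FALSE))
  set.seed(8)
  et <- step_environment(envt, NULL)
  expect_true(et$novel)
  expect_equal(n_env_states(et$env), 3L)  # not persisted
  expect_match(et$label, "^novelT")
})

test_that("constrained steps stay in the permitted set and flag infeasibility", {
  envb <- generate_environment(env_spec(seq_length = 4, branch_positions = 2,
                                        branch_arity = 2, dim = 8, noise_sd = 0, seed = 4))
  branch_state <- which(lengths(envb$succ) == 2)
  kids <- envb$succ[[branch_state]]
  set.seed(9)
  for (i in 1:20) {
    es <- step_environment(envb, branch_state, constrain_to = kids[2])
    expect_equal(es$state, kids[2])
  }
  # empty constrained support (neither a successor nor a start): infeasible
  far <- setdiff(seq_len(n_env_states(envb)), c(kids, envb$starts, branch_state))[1]
  es2 <- step_environment(envb, branch_state, constrain_to = far)
  expect_true(es2$infeasible)
  expect_true(es2$restarted)  # documented fallback: unconstrained restart
})

test_that("deprivation emissions are endogenous noise matching the chi-square tail", {
  dep <- deprivation_environment(dim = 8, noise_sd_endo = 1, seed = 11)
  e <- dep
  norms <- numeric(1000)
  for (i in 1:1000) { em <- emit(e, 1); e <- em$env; norms[i] <- sqrt(sum(em$stimulus^2)) }
  # at an ordinary novelty radius every emission is far from the (empty) known set
  expect_true(all(norms > 0.5))
  expect_lt(abs(mean(norms > 3) - (1 - stats::pchisq(9, df = 8))), 0.05)
  # reproducible
  e2 <- deprivation_environment(dim = 8, noise_sd_endo = 1, seed = 11)
  expect_identical(emit(e2, 1)$stimulus, emit(dep, 1)$stimulus)
  expect_error(deprivation_environment(8, 0, 1), "noise_sd_endo > 0")
})

test_that("the amulet transform splits shared states and kills branch uncertainty", {
  env <- generate_environment(env_spec(n_sequences = 1, seq_length = 4,
                                       branch_positions = 2, branch_arity = 2,
                                       dim = 8, noise_sd = 0, seed = 12))
  # the two sequences share their first two states
  shared <- intersect(env$seq_paths[[1]], env$seq_paths[[2]])
  expect_gte(length(shared), 2)
  env2 <- transform_amulets(env)
  expect_equal(length(intersect(env2$seq_paths[[1]], env2$seq_paths[[2]])), 0)
  expect_equal(env2$dim, env$dim + 2)
  expect_gte(min_pairwise_dist(env2$proto), env$min_sep)
  # after memorization the former branch point is deterministic
  g <- memorize_environment(env2)
  p <- env2$seq_paths[[1]]
  ctx <- vapply(p[1:2], function(s) classify(g, env2$proto[s, ], 0.45)$item_id, integer(1))
  expect_equal(entropy(option_set(g, ctx)), 0)
  # single-chain environment: topology unchanged
  chain <- generate_environment(env_spec(seq_length = 4, seed = 13))
  chain2 <- transform_amulets(chain)
  expect_equal(lengths(chain2$succ), lengths(chain$succ))
  expect_equal(length(chain2$starts), 1L)
})

test_that("branch-to-start moves the choice to sequence index 0", {
  env <- generate_environment(env_spec(n_sequences = 1, seq_length = 6,
                                       branch_positions = 3, branch_arity = 2,
                                       dim = 8, noise_sd = 0, seed = 14))
  env2 <- transform_branch_to_start(env)
  # distinct start states now carry the branch choice
  expect_equal(length(env2$starts), 2L)
  expect_false(env2$seq_paths[[1]][1] == env2$seq_paths[[2]][1])
  # branchless environment: identity
  chain <- generate_environment(env_spec(seq_length = 5, seed = 15))
  expect_equal(transform_branch_to_start(chain)$seq_paths, chain$seq_paths)
  # the memorized uncertainty profile peaks at step 0 after the transform
  unc_profile <- function(e) {
    g <- memorize_environment(e)
    p <- e$seq_paths[[1]]
    ctx <- integer(0)
    vapply(seq_along(p), function(i) {
      cls <- classify(g, e$proto[p[i], ], 0.45)
      u <- predictive_uncertainty(g, cls, c(ctx, cls$item_id))
      ctx <<- c(ctx, cls$item_id)
      u
    }, numeric(1))
  }
  # drop the terminal step: with no registered continuation it falls back to
  # H(M) in both environments, masking the branch structure of interest
  before <- utils::head(unc_profile(env), -1)
  after <- utils::head(unc_profile(env2), -1)
  expect_gt(before[3], 0)
  expect_equal(which.max(before), 3L)
  expect_true(all(after == 0))
  # ... and the entry choice carries the bit instead
  g2 <- memorize_environment(env2)
  expect_equal(entropy(option_set(g2, integer(0))), 1)
})

test_that("option limiting prunes to nu_max and lowers memorized branch entropy", {
  env8 <- generate_environment(env_spec(n_sequences = 1, seq_length = 4,
                                        branch_positions = 2, branch_arity = 8,
                                        dim = 16, noise_sd = 0, seed = 16))
  g8 <- memorize_environment(env8)
  p <- env8$seq_paths[[1]]
  ctx <- vapply(p[1:2], function(s) classify(g8, env8$proto[s, ], 0.45)$item_id, integer(1))
  expect_equal(entropy(option_set(g8, ctx)), 3)

  env2 <- transform_limit_options(env8, 2)
  expect_equal(length(env2$seq_paths), 2L)
  expect_true(all(lengths(env2$succ) <= 2))
  g2 <- memorize_environment(env2)
  ctx2 <- vapply(env2$seq_paths[[1]][1:2], function(s)
    classify(g2, env2$proto[s, ], 0.45)$item_id, integer(1))
  expect_equal(entropy(option_set(g2, ctx2)), 1)
  # no-op when the cap is not binding
  expect_equal(transform_limit_options(env8, 8)$seq_paths, env8$seq_paths)
})

test_that("transforms are pure functions of their inputs", {
  env <- preset_environment("branching", seed = 17)
  expect_identical(env_hash(transform_amulets(env)), env_hash(transform_amulets(env)))
  expect_identical(env_hash(transform_branch_to_start(env)),
                   env_hash(transform_branch_to_start(env)))
  expect_identical(env_hash(transform_limit_options(env, 1)),
                   env_hash(transform_limit_options(env, 1)))
})
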