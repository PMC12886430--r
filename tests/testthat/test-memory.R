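# Memory graph: nearest-neighbour classification, sequence bookkeeping, the
# surprise / uncertainty / disappointment computations, and serialization.

test_that("classification is nearest-neighbour with a novelty radius", {
  P <- grid_protos(3, d = 4, scale = 10)
  g <- memory_from_paths(P, list(1:3))
  # exact match: that item, distance 0, known
  cls <- classify(g, P[2, ], 0.5)
  expect_equal(cls$item_id, 2L)
  expect_equal(cls$distance, 0)
  expect_false(cls$is_new)
  # small perturbation within the radius leaves the outcome unchanged
  cls2 <- classify(g, P[2, ] + c(0.1, -0.1, 0.05, 0), 0.5)
  expect_equal(cls2$item_id, 2L)
  expect_false(cls2$is_new)
  # far stimulus: nearest item still returned, flagged new
  far <- P[1, ] + 100
  cls3 <- classify(g, far, 0.5)
  expect_false(is.na(cls3$item_id))
  expect_true(cls3$is_new)
  # empty memory
  cls4 <- classify(memory_graph(4), P[1, ], 0.5)
  expect_true(is.na(cls4$item_id))
  expect_true(cls4$is_new)
  expect_error(classify(g, c(1, 2), 0.5), "dimension")
})

test_that("classification ties break to the lowest item id and are idempotent", {
  g <- memory_graph(2)
  g <- insert_observation(g, NA, c(0, 1), 0.1)$graph
  g <- insert_observation(g, NA, c(0, -1), 0.1)$graph
  cls <- classify(g, c(0, 0), 10)  # equidistant from both
  expect_equal(cls$item_id, 1L)
  for (i in seq_len(n_items(g))) {
    ci <- classify(g, g$prototypes[i, ], 0.1)
    expect_equal(ci$item_id, i)
    expect_equal(ci$distance, 0)
  }
})

test_that("insertion builds items, edges and the sequence registry", {
  P <- grid_protos(3, d = 4)
  g <- memory_graph(4)
  ins <- insert_observation(g, NA, P[1, ], 0.5)
  expect_equal(n_items(ins$graph), 1L)
  expect_equal(ins$graph$counts, 1L)
  # the a -> b -> c chain inserted twice: 3 items, 2 edges, every count 2
  g2 <- memory_from_paths(P, list(1:3), times = 2)
  expect_equal(n_items(g2), 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$edges$count, c(2L, 2L))
  expect_equal(g2$counts, c(2L, 2L, 2L))
  expect_equal(length(g2$sequences), 2L)
  expect_equal(g2$sequences[[1]], g2$sequences[[2]])
})

test_that("memory only ever grows under insertion", {
  set.seed(21)
  g <- memory_graph(3)
  last_items <- 0L; last_seqs <- 0L
  for (i in 1:40) {
    g <- insert_observation(g, NA, stats::rnorm(3, sd = 5), 0.2)$graph
    if (i %% 8 == 0) g <- close_sequence(g)
    expect_gte(n_items(g), last_items)
    expect_gte(length(g$sequences), last_seqs)
    last_items <- n_items(g); last_seqs <- length(g$sequences)
  }
})

test_that("option sets follow depth-limited suffix matching of the registry", {
  P <- grid_protos(5, d = 6)
  # two sequences: 1-2-3 and 4-2-5 (shared middle item)
  g <- memory_from_paths(P, list(c(1, 2, 3), c(4, 2, 5)))
  # chain interior: point mass, zero entropy
  os <- option_set(g, c(1L, 2L))
  expect_equal(os$outcomes, "3")
  expect_equal(entropy(os), 0)
  # Markov mode forgets which sequence we are in: uniform over both successors
  os1 <- option_set(g, c(1L, 2L), depth = 1)
  expect_setequal(os1$outcomes, c("3", "5"))
  expect_equal(entropy(os1), 1)
  # no registered continuation: empty distribution
  expect_equal(length(option_set(g, c(3L))$outcomes), 0)
  # empty context: options over sequence starts
  expect_setequal(option_set(g, integer(0))$outcomes, c("1", "4"))
  expect_error(option_set(g, 99L), "unknown item")
})

test_that("a nu-way equally counted branch carries log2(nu) bits of option entropy", {
  P <- grid_protos(6, d = 8)
  g <- memory_from_paths(P, list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5), c(1, 2, 6)))
  os <- option_set(g, c(1L, 2L))
  expect_equal(length(os$outcomes), 4L)
  expect_equal(entropy(os), 2)
})

test_that("predictive uncertainty covers the deterministic, branch and novel cases", {
  P <- grid_protos(6, d = 8)
  g <- memory_from_paths(P, list(c(1, 2, 3), c(1, 2, 4)))
  # deterministic continuation
  expect_equal(predictive_uncertainty(g, known_cls(g, 1), c(1L)), 0)
  # 2-way branch
  expect_equal(predictive_uncertainty(g, known_cls(g, 2), c(1L, 2L)), 1)
  # new stimulus: the count-weighted memory entropy
  expect_equal(predictive_uncertainty(g, new_cls(), integer(0)),
               memory_entropy(g))
})

test_that("perceptual surprise mixes option entropy with the novelty baseline", {
  P <- grid_protos(6, d = 8)
  chain <- memory_from_paths(P, list(1:4))
  expect_equal(perceptual_surprise(chain, c(1L), baseline_bits = 3), 0)
  expect_equal(perceptual_surprise(chain, c(4L), baseline_bits = 3), 3)  # no continuation
  branchy <- memory_from_paths(P, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(perceptual_surprise(branchy, c(1L), baseline_bits = 3), 2)
  expect_equal(perceptual_surprise(branchy, c(1L), baseline_bits = 3, novelty_mass = 0.25),
               0.75 * 2 + 0.25 * 3)
})

test_that("realized surprisal follows the smoothing closed forms", {
  P <- grid_protos(6, d = 8)
  lam <- 2^-10
  chain <- memory_from_paths(P, list(1:4))
  # unique memorized continuation observed
  expect_equal(surprisal_of(chain, c(1L), known_cls(chain, 2), baseline_bits = 3,
                            novelty_mass = lam),
               -log2(1 - lam), tolerance = 1e-12)
  # unseen continuation: novelty mass spread over (items not among the
  # options) + 1 brand-new slot; here 4 items, 1 option -> 4 slots
  expect_equal(surprisal_of(chain, c(1L), new_cls(), baseline_bits = 3,
                            novelty_mass = lam),
               -log2(lam / 4), tolerance = 1e-12)
  # one of 2 equally counted continuations, vanishing smoothing: 1 bit
  branchy <- memory_from_paths(P, list(c(1, 2), c(1, 3)))
  expect_equal(surprisal_of(branchy, c(1L), known_cls(branchy, 2), baseline_bits = 3,
                            novelty_mass = 1e-12),
               1, tolerance = 1e-9)
  # no continuation at all: baseline fallback
  expect_equal(surprisal_of(chain, c(4L), known_cls(chain, 1), baseline_bits = 3,
                            novelty_mass = lam), 3)
  expect_equal(surprisal_of(memory_graph(8), integer(0), new_cls(),
                            baseline_bits = 3), 3)
})

test_that("disappointment conditions on the full memorized prefix", {
  P <- grid_protos(6, d = 8)
  g <- memory_from_paths(P, list(c(1, 2, 3)))
  # continuation as memorized
  d1 <- disappointment(g, c(1L, 2L), known_cls(g, 3))
  expect_false(d1$flag)
  expect_lt(d1$bits, 0.01)
  # a -> b -> d with d known elsewhere: deviation
  g2 <- memory_from_paths(P, list(c(1, 2, 3), c(4, 5)))
  d2 <- disappointment(g2, c(1L, 2L), known_cls(g2, 4))
  expect_true(d2$flag)
  expect_gt(d2$bits, 0)
  # two registered continuations of the shared prefix: either is fine, 1 bit
  g3 <- memory_from_paths(P, list(c(1, 2, 3), c(1, 2, 4)))
  for (obs in c(3L, 4L)) {
    d3 <- disappointment(g3, c(1L, 2L), known_cls(g3, obs), novelty_mass = 1e-12)
    expect_false(d3$flag)
    expect_equal(d3$bits, 1, tolerance = 1e-9)
  }
  # no matching prefix: documented fallback, no flag
  d4 <- disappointment(g, c(2L, 1L), known_cls(g, 3), baseline_bits = 3)
  expect_false(d4$flag)
  expect_equal(d4$bits, 3)
})

test_that("memory entropy is the count-weighted item entropy", {
  P <- grid_protos(4, d = 6)
  g1 <- memory_from_paths(P, list(c(1)))
  expect_equal(memory_entropy(g1), 0)
  g4 <- memory_from_paths(P, list(c(1), c(2), c(3), c(4)))
  expect_equal(memory_entropy(g4), 2)
  # counts (2,1,1): same as probs (0.5, 0.25, 0.25)
  g3 <- memory_from_paths(P, list(c(1), c(1), c(2), c(3)))
  expect_equal(memory_entropy(g3), 1.5)
  expect_equal(memory_entropy(g3, weighting = "uniform"), log2(3))
  expect_warning(h0 <- memory_entropy(memory_graph(2)), "empty")
  expect_equal(h0, 0)
})

test_that("an option set can be more uniform than the global item distribution", {
  # a memory dominated by one routine item, but with a 4-way uniform branch:
  # the per-realization conditional H(M_next | R = branch item) exceeds the
  # unconditional H(M)
  P <- grid_protos(5, d = 8)
  paths <- c(rep(list(c(1)), 60), list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  g <- memory_from_paths(P, paths)
  branch_h <- predictive_uncertainty(g, known_cls(g, 1), c(1L))
  expect_equal(branch_h, 2)
  expect_lt(memory_entropy(g), branch_h)
})

test_that("memory export/import round trips are lossless in JSON and GraphML", {
  P <- grid_protos(3, d = 4)
  g <- memory_from_paths(P, list(1:3), times = 2)
  g2 <- import_memory(export_memory(g, format = "json"))
  expect_equal(g2, g)
  tf <- tempfile(fileext = ".graphml")
  export_memory(g, tf, "graphml")
  g3 <- import_memory(tf)
  expect_equal(g3$prototypes, g$prototypes)
  expect_equal(g3$counts, g$counts)
  expect_equal(g3$sequences, g$sequences)
  expect_equal(g3$edges[order(g3$edges$from), ], g$edges[order(g$edges$from), ],
               ignore_attr = TRUE)
})

test_that("a large random memory survives the round trip with all counts intact", {
  set.seed(99)
  g <- memory_graph(5)
  for (s in 1:10) {
    prev <- NA_integer_
    for (i in 1:10) {
      ins <- insert_observation(g, prev, stats::rnorm(5, sd = 8), 0.2)
      g <- ins$graph; prev <- ins$item_id
    }
    g <- close_sequence(g)
  }
  expect_gte(n_items(g), 90)  # ~100 nodes; a few chance re-classifications allowed
  tf <- tempfile(fileext = ".graphml")
  export_memory(g, tf, "graphml")
  g2 <- import_memory(tf)
  expect_equal(g2$counts, g$counts)
  expect_equal(sort(g2$edges$count), sort(g$edges$count))
  expect_equal(g2$sequences, g$sequences)
  expect_equal(g2$prototypes, g$prototypes, tolerance = 1e-12)
})

test_that("malformed memory documents are rejected with location info", {
  doc <- list(format = "entrosim-memory", version = 1, dim = 2,
              items = list(list(id = 1, prototype = c(0, 0), count = 1)),
              edges = list(list(from = 1, to = 7, count = 1)),
              sequences = list(), open = integer(0))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  expect_error(import_memory(as.character(txt)), "dangling edge")
  expect_error(import_memory('{"format":"other"}'), "not an entrosim memory")
})
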