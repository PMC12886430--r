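## The agent's memory M: an append-only directed graph of classified stimulus
## prototypes with a registry of complete memorized sequences, plus the
## nearest-neighbour classifier rho and the surprise / uncertainty /
## disappointment computations that condition on it.

#' Create an empty memory graph
#'
#' The memory stores one prototype vector per item, an observation count per
#' item, directed transition edges with counts, and a registry of complete
#' memorized item-id sequences. Memory is append-only: there is no deletion
#' operation, reflecting its persistent character.
#'
#' @param dim dimension of the stimulus/prototype vectors.
#' @return an object of class `memory_graph`.
#' @export
memory_graph <- function(dim) {
  stopifnot(is.numeric(dim), dim >= 1)
  structure(list(
    dim = as.integer(dim),
    prototypes = matrix(numeric(0), nrow = 0, ncol = as.integer(dim)),
    counts = integer(0),
    edges = data.frame(from = integer(0), to = integer(0), count = integer(0)),
    sequences = list(),
    open = integer(0)
  ), class = "memory_graph")
}

#' Number of items stored in a memory graph
#' @param g a [memory_graph()].
#' @export
n_items <- function(g) nrow(g$prototypes)

#' @export
print.memory_graph <- function(x, ...) {
  cat("<memory_graph: ", n_items(x), " items (dim ", x$dim, "), ",
      nrow(x$edges), " edges, ", length(x$sequences),
      " registered sequences>\n", sep = "")
  invisible(x)
}

check_item_ids <- function(g, ids) {
  bad <- ids[ids < 1 | ids > n_items(g)]
  if (length(bad)) stopf("unknown item id(s): %s", paste(bad, collapse = ", "))
}

#' Nearest-neighbour classification of a stimulus
#'
#' Maps a raw stimulus to the closest stored prototype under Euclidean
#' distance. The nearest item is returned regardless of how far it is; the
#' `is_new` flag marks the stimulus as novel when that distance exceeds the
#' novelty radius (or the memory is empty). Ties break to the lowest item id
#' for determinism.
#'
#' @param g a [memory_graph()].
#' @param stimulus numeric vector of length `g$dim`.
#' @param novelty_radius positive radius within which a stimulus counts as a
#'   (noisy) observation of a known prototype.
#' @return an object of class `classification`: `item_id` (NA when memory is
#'   empty), `distance`, `is_new`.
#' @export
classify <- function(g, stimulus, novelty_radius) {
  stopifnot(inherits(g, "memory_graph"), novelty_radius > 0)
  if (length(stimulus) != g$dim)
    stopf("stimulus dimension %d != memory dimension %d", length(stimulus), g$dim)
  if (n_items(g) == 0L) {
    res <- list(item_id = NA_integer_, distance = Inf, is_new = TRUE)
  } else {
    d2 <- rowSums((g$prototypes - matrix(stimulus, n_items(g), g$dim, byrow = TRUE))^2)
    i <- which.min(d2)  # which.min takes the first (lowest id) on ties
    dist <- sqrt(d2[i])
    res <- list(item_id = as.integer(i), distance = dist,
                is_new = dist > novelty_radius)
  }
  structure(res, class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification: item ", x$item_id, ", distance ",
      signif(x$distance, 4), if (x$is_new) " (NEW)>" else ">", "\n", sep = "")
  invisible(x)
}

#' Insert an observation into memory
#'
#' Classifies the stimulus; if novel, a new item is created with the stimulus
#' as its prototype, otherwise the matched item's count is incremented. A
#' directed edge from `prev_item_id` (when given) is created or incremented,
#' and the open (in-progress) sequence is extended. Call [close_sequence()]
#' at a sequence boundary to move the open path into the registry.
#'
#' @inheritParams classify
#' @param prev_item_id id of the preceding item in the current sequence, or
#'   `NA` at a sequence start.
#' @return list with elements `graph` (updated memory), `item_id`, and
#'   `classification`.
#' @export
insert_observation <- function(g, prev_item_id, stimulus, novelty_radius) {
  cls <- classify(g, stimulus, novelty_radius)
  if (cls$is_new) {
    g$prototypes <- rbind(g$prototypes, matrix(as.numeric(stimulus), 1))
    g$counts <- c(g$counts, 1L)
    id <- n_items(g)
  } else {
    id <- cls$item_id
    g$counts[id] <- g$counts[id] + 1L
  }
  if (!is.na(prev_item_id)) {
    check_item_ids(g, prev_item_id)
    k <- which(g$edges$from == prev_item_id & g$edges$to == id)
    if (length(k)) g$edges$count[k] <- g$edges$count[k] + 1L
    else g$edges <- rbind(g$edges, data.frame(from = as.integer(prev_item_id),
                                              to = id, count = 1L))
  }
  g$open <- c(g$open, id)
  list(graph = g, item_id = id, classification = cls)
}

#' Close the open sequence and register it
#'
#' Moves the in-progress item path into the sequence registry (no-op when the
#' open path is empty). Registered sequences are what the option-set and
#' disappointment computations condition on.
#'
#' @param g a [memory_graph()].
#' @return the updated memory graph.
#' @export
close_sequence <- function(g) {
  if (length(g$open) > 0) {
    g$sequences[[length(g$sequences) + 1L]] <- g$open
    g$open <- integer(0)
  }
  g
}

#' Register an item-id sequence directly
#'
#' Low-level hook used e.g. when hypothetically learning a therapy candidate
#' on a copied memory: registers the path and increments the corresponding
#' edge counts (item counts are incremented too, keeping node/edge counts
#' consistent with one traversal of the path).
#'
#' @param g a [memory_graph()].
#' @param ids integer item ids forming a path.
#' @return the updated memory graph.
#' @export
register_sequence <- function(g, ids) {
  check_item_ids(g, ids)
  g$counts[ids] <- g$counts[ids] + 1L
  if (length(ids) > 1) for (i in seq_len(length(ids) - 1L)) {
    k <- which(g$edges$from == ids[i] & g$edges$to == ids[i + 1L])
    if (length(k)) g$edges$count[k] <- g$edges$count[k] + 1L
    else g$edges <- rbind(g$edges, data.frame(from = ids[i], to = ids[i + 1L], count = 1L))
  }
  g$sequences[[length(g$sequences) + 1L]] <- as.integer(ids)
  g
}

## Counts of registered continuations after a context.
## anchor = "suffix": depth-limited suffix matching anywhere in a sequence
##   (empty context matches sequence starts: the option set over entry points).
## anchor = "prefix": the context must be a prefix of the whole sequence
##   (the full-history conditioning behind disappointment).
continuation_counts <- function(g, context, depth = Inf, anchor = c("suffix", "prefix")) {
  anchor <- match.arg(anchor)
  check_item_ids(g, context)
  counts <- integer(0); names(counts) <- character(0)
  bump <- function(counts, id) {
    key <- as.character(id)
    counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
    counts
  }
  if (anchor == "prefix") {
    k <- length(context)
    for (s in g$sequences) {
      if (length(s) > k && (k == 0L || identical(s[seq_len(k)], as.integer(context))))
        counts <- bump(counts, s[k + 1L])
    }
    return(counts)
  }
  suf <- if (is.finite(depth)) utils::tail(context, depth) else context
  k <- length(suf)
  for (s in g$sequences) {
    if (k == 0L) {
      if (length(s) > 0) counts <- bump(counts, s[1L])
    } else if (length(s) > k) {
      for (i in k:(length(s) - 1L)) {
        if (identical(s[(i - k + 1L):i], as.integer(suf)))
          counts <- bump(counts, s[i + 1L])
      }
    }
  }
  counts
}

#' Memorized option set after a context
#'
#' The distribution over memorized successor items given the recent item-id
#' context, under depth-limited suffix matching against the sequence
#' registry; probabilities are proportional to transition (traversal) counts.
#' An empty context yields the options over sequence starts. An empty result
#' (no registered continuation) signals the novel/learning case in which the
#' memory carries no information about what comes next.
#'
#' @param g a [memory_graph()].
#' @param context integer vector of item ids (most recent last).
#' @param depth maximum suffix length used for matching; `Inf` (default)
#'   matches on the full context, `1` gives the Markov (last-item-only) mode.
#' @return a [finite_distribution()] over successor item ids; zero-length
#'   when no continuation is registered.
#' @export
option_set <- function(g, context, depth = Inf) {
  stopifnot(inherits(g, "memory_graph"), depth >= 1 || length(context) == 0 || is.infinite(depth))
  counts <- continuation_counts(g, context, depth, "suffix")
  if (length(counts) == 0L)
    return(finite_distribution(character(0), numeric(0)))
  finite_distribution(names(counts), as.numeric(counts) / sum(counts))
}

#' Entropy of the memory-item distribution H(M)
#'
#' The fallback uncertainty when a stimulus is new (or no continuation is
#' memorized): the entropy of the distribution over all stored items,
#' count-weighted by default.
#'
#' @param g a [memory_graph()].
#' @param weighting `"counts"` (observation-frequency weights, default) or
#'   `"uniform"`.
#' @return bits; 0 (with a warning) for an empty memory.
#' @export
memory_entropy <- function(g, weighting = c("counts", "uniform")) {
  stopifnot(inherits(g, "memory_graph"))
  weighting <- match.arg(weighting)
  if (n_items(g) == 0L) {
    warning("memory is empty; H(M) defined as 0")
    return(0)
  }
  w <- if (weighting == "counts") g$counts else rep(1, n_items(g))
  shannon_bits(w / sum(w))
}

#' Predictive uncertainty H(M|R = r)
#'
#' The prediction-phase uncertainty given the current classified stimulus:
#' the entropy of the memorized option set when the stimulus is known and a
#' continuation is registered (0 bits on a deterministic continuation,
#' `log2(nu)` on a nu-way uniform branch), and the full memory entropy H(M)
#' when the stimulus is new or no continuation exists.
#'
#' @param g a [memory_graph()].
#' @param r_classified a `classification` (see [classify()]).
#' @param context item-id context *including* the current item when known.
#' @param depth suffix-match depth, see [option_set()].
#' @param weighting passed to [memory_entropy()] for the fallback.
#' @return bits.
#' @export
predictive_uncertainty <- function(g, r_classified, context, depth = Inf,
                                   weighting = c("counts", "uniform")) {
  weighting <- match.arg(weighting)
  if (n_items(g) == 0L || isTRUE(r_classified$is_new))
    return(if (n_items(g) == 0L) 0 else memory_entropy(g, weighting))
  opts <- option_set(g, context, depth)
  if (length(opts$outcomes) == 0L) return(memory_entropy(g, weighting))
  entropy(opts)
}

#' Perceptual surprise H(R|M = m)
#'
#' The perception-phase surprise given the memorized context: the entropy of
#' the memory-predicted next-stimulus distribution, optionally mixed with a
#' novelty mass assigned the environment baseline,
#' `(1 - lambda) * H(options) + lambda * baseline_bits`. With `lambda = 0`
#' this reduces exactly to the deterministic (0 bits) and branch
#' (`log2(nu)` bits) cases; when no continuation is memorized the surprise
#' falls back to `baseline_bits`, the agent's stand-in for H(R).
#'
#' @param g a [memory_graph()].
#' @param context item-id context (most recent last).
#' @param depth suffix-match depth, see [option_set()].
#' @param baseline_bits the configured H(R) proxy, typically
#'   `log2(environment alphabet size)`.
#' @param novelty_mass mixing weight `lambda` in `[0, 1]` for the novel
#'   continuation; default 0.
#' @return bits.
#' @export
perceptual_surprise <- function(g, context, depth = Inf, baseline_bits,
                                novelty_mass = 0) {
  stopifnot(baseline_bits >= 0, novelty_mass >= 0, novelty_mass <= 1)
  opts <- option_set(g, context, depth)
  if (length(opts$outcomes) == 0L) return(baseline_bits)
  (1 - novelty_mass) * entropy(opts) + novelty_mass * baseline_bits
}

## Smoothed probability the memory assigns to an observed next item, given
## continuation counts. novelty_mass is reserved for the unseen slots: the
## memory items not among the continuations plus one brand-new slot.
smoothed_prob <- function(g, counts, observed, novelty_mass) {
  n_opts <- length(counts)
  n_unseen <- n_items(g) - n_opts + 1L
  if (isTRUE(observed$is_new) || !as.character(observed$item_id) %in% names(counts))
    return(novelty_mass / n_unseen)
  (1 - novelty_mass) * counts[[as.character(observed$item_id)]] / sum(counts)
}

#' Realized surprisal of an observed stimulus
#'
#' The per-event score compared against the sensory-overload threshold under
#' the `realized_surprisal` event rule: `-log2` of the smoothed probability
#' the memory assigns to the observed next item. Known continuations share
#' probability `1 - novelty_mass` proportionally to their counts; the
#' remaining `novelty_mass` is spread uniformly over the unseen slots (items
#' not among the continuations, plus one brand-new slot), so the score is
#' finite for every input. With no memorized continuation at all the score
#' falls back to `baseline_bits`.
#'
#' @inheritParams perceptual_surprise
#' @param observed a `classification` of the incoming stimulus.
#' @param novelty_mass smoothing mass in (0, 1) reserved for unseen
#'   continuations.
#' @return bits (finite).
#' @export
surprisal_of <- function(g, context, observed, depth = Inf, baseline_bits,
                         novelty_mass = 2^-10) {
  stopifnot(novelty_mass > 0, novelty_mass < 1)
  if (n_items(g) == 0L) return(baseline_bits)
  counts <- continuation_counts(g, context, depth, "suffix")
  if (length(counts) == 0L) return(baseline_bits)
  -log2(smoothed_prob(g, counts, observed, novelty_mass))
}

#' Disappointment: deviation from the fully memorized sequence prefix
#'
#' Conditions on the *entire* item history of the current sequence (not just
#' the recent suffix): the flag is raised when the observed item deviates
#' from every registered continuation of that full prefix — the sequence does
#' not continue the way it was memorized. The score is the realized surprisal
#' at full depth under the same smoothing as [surprisal_of()]. When no
#' registered sequence has the context as a prefix, the flag is `FALSE` and
#' the score falls back to `baseline_bits` (no memorized expectation exists
#' to be disappointed about).
#'
#' @inheritParams surprisal_of
#' @param full_context the complete item-id history of the current sequence.
#' @return list with `flag` (logical) and `bits`.
#' @export
disappointment <- function(g, full_context, observed, baseline_bits = 0,
                           novelty_mass = 2^-10) {
  counts <- continuation_counts(g, full_context, Inf, "prefix")
  if (length(counts) == 0L)
    return(list(flag = FALSE, bits = baseline_bits))
  deviates <- isTRUE(observed$is_new) ||
    !as.character(observed$item_id) %in% names(counts)
  list(flag = deviates, bits = -log2(smoothed_prob(g, counts, observed, novelty_mass)))
}
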