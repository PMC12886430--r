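## Guideline-inspired environment transforms: countermeasures against
## branch-point uncertainty. "Amulets" make otherwise-shared states distinct
## per sequence; moving branches to sequence beginnings front-loads the
## choice; option limiting prunes branch alternatives.

#' Amulet transform: disambiguate shared states per sequence
#'
#' Appends one indicator coordinate per sequence to every prototype and
#' duplicates states shared between sequences, so each full sequence becomes
#' pairwise distinct from the first stimulus on. After memorization the
#' option set at a former branch point is a point mass: the branch
#' uncertainty drops to 0 bits. The pairwise separation invariant is
#' preserved (the indicator magnitude equals `min_sep`).
#'
#' @param env an `env_model` (non-deprivation).
#' @return the transformed `env_model` (dimension grows by the number of
#'   sequences).
#' @export
transform_amulets <- function(env) {
  stopifnot(inherits(env, "env_model"), !env$deprivation)
  np <- length(env$seq_paths)
  d2 <- env$dim + np
  proto <- matrix(numeric(0), 0, d2)
  labels <- character(0)
  paths <- vector("list", np)
  a <- env$min_sep
  nid <- 0L
  for (j in seq_len(np)) {
    p <- env$seq_paths[[j]]
    newp <- integer(length(p))
    for (i in seq_along(p)) {
      nid <- nid + 1L
      row <- c(env$proto[p[i], ], rep(0, np))
      row[env$dim + j] <- a
      proto <- rbind(proto, row)
      labels[nid] <- paste0(env$labels[p[i]], "_am", j)
      newp[i] <- nid
    }
    paths[[j]] <- newp
  }
  rownames(proto) <- NULL
  env$dim <- d2; env$proto <- proto; env$labels <- labels
  env$seq_paths <- paths
  env_finalize(env)
}

#' Move branch points to the sequence beginnings
#'
#' Reorders every sequence so that its distinguishing states (those not
#' shared with any other sequence) come first, followed by the shared
#' states; the branch choice is thereby made at sequence index 0, after
#' which a full-context agent faces no residual branch uncertainty. States
#' and emission semantics are unchanged; only sequence order and hence the
#' transition structure move. Branchless environments are returned
#' unchanged.
#'
#' @param env an `env_model`.
#' @return the transformed `env_model`.
#' @export
transform_branch_to_start <- function(env) {
  stopifnot(inherits(env, "env_model"))
  membership <- table(unlist(lapply(env$seq_paths, unique)))
  shared_ids <- as.integer(names(membership)[membership > 1])
  env$seq_paths <- lapply(env$seq_paths, function(p) {
    own <- !(p %in% shared_ids)
    c(p[own], p[!own])
  })
  env_finalize(env)
}

#' Limit the number of options at branch points
#'
#' Prunes the lowest-probability successors of every state (and the
#' lowest-probability start states) down to at most `nu_max` alternatives,
#' renormalizing; ties break to the lowest state id. Sequences traversing a
#' pruned transition are dropped and the remaining sequence weights
#' renormalized. A memorized nu-way uniform branch thus drops from
#' `log2(nu)` to `log2(nu_max)` bits of uncertainty.
#'
#' @param env an `env_model`.
#' @param nu_max maximum number of alternatives to keep (`>= 1`).
#' @return the transformed `env_model`; identity when no out-degree exceeds
#'   `nu_max`.
#' @export
transform_limit_options <- function(env, nu_max) {
  stopifnot(inherits(env, "env_model"), nu_max >= 1)
  keep_top <- function(ids, w) {
    if (length(ids) <= nu_max) return(ids)
    ord <- order(-w, ids)  # highest weight first, lowest id on ties
    ids[ord[seq_len(nu_max)]]
  }
  kept_edges <- new.env(parent = emptyenv())
  for (s in seq_along(env$succ)) {
    kept <- keep_top(env$succ[[s]], env$succ_prob[[s]])
    for (b in kept) kept_edges[[paste(s, b)]] <- TRUE
  }
  kept_starts <- keep_top(env$starts, env$start_probs)
  ok <- vapply(env$seq_paths, function(p) {
    if (!(p[1] %in% kept_starts)) return(FALSE)
    if (length(p) > 1) for (i in seq_len(length(p) - 1L))
      if (is.null(kept_edges[[paste(p[i], p[i + 1L])]])) return(FALSE)
    TRUE
  }, logical(1))
  if (!any(ok)) stopf("option limit nu_max=%d leaves no feasible sequence", nu_max)
  env$seq_paths <- env$seq_paths[ok]
  env$path_w <- env$path_w[ok] / sum(env$path_w[ok])
  env_finalize(env)
}
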