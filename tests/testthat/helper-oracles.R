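# Independent direct-summation oracles for the information quantities, kept
# deliberately separate from the package's implementation route
# (H(X|Y) = H(X,Y) - H(Y) there; explicit double sums here).

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

oracle_entropy <- function(p) -sum(plogp(p))

# H(X|Y) from a joint matrix P (rows = X), by direct double summation of
# -p(x,y) log2 p(x|y)
oracle_cond_entropy_rows_given_cols <- function(P) {
  P <- unname(P)
  py <- colSums(P)
  h <- 0
  for (y in seq_len(ncol(P))) {
    if (py[y] <= 0) next
    for (x in seq_len(nrow(P))) {
      if (P[x, y] > 0) h <- h - P[x, y] * log2(P[x, y] / py[y])
    }
  }
  h
}

oracle_mi <- function(P) {
  P <- unname(P)
  px <- rowSums(P); py <- colSums(P)
  s <- 0
  for (x in seq_len(nrow(P))) for (y in seq_len(ncol(P)))
    if (P[x, y] > 0) s <- s + P[x, y] * log2(P[x, y] / (px[x] * py[y]))
  s
}

oracle_dh <- function(P) {
  oracle_cond_entropy_rows_given_cols(P) +
    oracle_cond_entropy_rows_given_cols(t(P))
}

random_joint <- function(nr, nc) {
  P <- matrix(stats::runif(nr * nc), nr, nc)
  P <- P / sum(P)
  joint_distribution(paste0("r", seq_len(nr)), paste0("m", seq_len(nc)), P)
}

# Memory holding the sequences given as lists of prototype row indices into
# `proto`; every traversal goes through the public insertion API.
memory_from_paths <- function(proto, paths, eps = 0.45, times = 1) {
  g <- memory_graph(ncol(proto))
  for (rep in seq_len(times)) for (p in paths) {
    prev <- NA_integer_
    for (s in p) {
      ins <- insert_observation(g, prev, proto[s, ], eps)
      g <- ins$graph
      prev <- ins$item_id
    }
    g <- close_sequence(g)
  }
  g
}

# Well-separated deterministic prototype matrix: k rows, coordinates on a
# scaled identity-like grid (pairwise distance >= scale).
grid_protos <- function(k, d = max(4, k), scale = 10) {
  P <- matrix(0, k, d)
  for (i in seq_len(k)) P[i, ((i - 1) %% d) + 1] <- scale * (1 + (i - 1) %/% d)
  P
}

known_cls <- function(g, id) structure(list(item_id = as.integer(id), distance = 0,
                                            is_new = FALSE), class = "classification")
new_cls <- function() structure(list(item_id = NA_integer_, distance = Inf,
                                     is_new = TRUE), class = "classification")
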