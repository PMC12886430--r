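## Discrete probability objects and the information-theoretic quantities the
## simulator is built on: entropy, conditional entropy, joint entropy, mutual
## information, and the entropy distance D_H(R,M) = H(R|M) + H(M|R)
## (variation of information). All quantities are in bits (log base 2).

PROB_TOL <- 1e-9

#' Finite discrete distribution
#'
#' A probability distribution over a finite set of opaque symbols. Zero
#' probabilities are permitted; duplicate outcomes and negative probabilities
#' are not. An empty distribution (no outcomes) is allowed as the degenerate
#' "no options" object returned by [option_set()] when the memory offers no
#' continuation.
#'
#' @param outcomes vector of outcome labels (coerced to character, must be
#'   unique).
#' @param probs numeric vector of the same length; non-negative, summing to 1
#'   within `1e-9` (unless empty).
#' @return an object of class `finite_distribution` with fields `outcomes`
#'   and `probs`.
#' @examples
#' entropy(finite_distribution(letters[1:4], rep(0.25, 4)))  # 2 bits
#' @export
finite_distribution <- function(outcomes, probs) {
  outcomes <- as.character(outcomes)
  probs <- as.numeric(probs)
  if (length(outcomes) != length(probs))
    stopf("outcomes and probs must have equal length")
  if (anyDuplicated(outcomes))
    stopf("duplicate outcomes are not allowed")
  if (any(probs < -PROB_TOL))
    stopf("negative probability")
  if (length(probs) > 0 && abs(sum(probs) - 1) > PROB_TOL)
    stopf("probabilities must sum to 1 (got %.12f)", sum(probs))
  structure(list(outcomes = outcomes, probs = pmax(probs, 0)),
            class = "finite_distribution")
}

#' @export
print.finite_distribution <- function(x, ...) {
  cat("<finite_distribution over", length(x$outcomes), "outcomes>\n")
  if (length(x$outcomes)) {
    df <- data.frame(outcome = x$outcomes, prob = round(x$probs, 6))
    print(utils::head(df, 10), row.names = FALSE)
    if (length(x$outcomes) > 10) cat("...\n")
  }
  invisible(x)
}

#' Joint distribution of an (R, M) pair
#'
#' Houses the environment/memory pair over which the entropy distance, the
#' conditional entropies (surprise and uncertainty), and the mutual
#' information are computed. Rows index R outcomes, columns index M outcomes.
#'
#' @param r_outcomes,m_outcomes outcome labels for the two variables.
#' @param probs matrix of non-negative cell probabilities (rows = R), summing
#'   to 1 within `1e-9`.
#' @return an object of class `joint_distribution`.
#' @export
joint_distribution <- function(r_outcomes, m_outcomes, probs) {
  r_outcomes <- as.character(r_outcomes)
  m_outcomes <- as.character(m_outcomes)
  probs <- as.matrix(probs)
  if (anyDuplicated(r_outcomes) || anyDuplicated(m_outcomes))
    stopf("duplicate outcomes are not allowed")
  if (nrow(probs) != length(r_outcomes) || ncol(probs) != length(m_outcomes))
    stopf("probs must be a %d x %d matrix", length(r_outcomes), length(m_outcomes))
  if (any(probs < -PROB_TOL)) stopf("negative probability")
  if (abs(sum(probs) - 1) > PROB_TOL)
    stopf("joint probabilities must sum to 1 (got %.12f)", sum(probs))
  probs <- pmax(probs, 0)
  dimnames(probs) <- list(r_outcomes, m_outcomes)
  structure(list(r_outcomes = r_outcomes, m_outcomes = m_outcomes, probs = probs),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat("<joint_distribution ", length(x$r_outcomes), " x ", length(x$m_outcomes),
      ">  H(R,M) = ", round(joint_entropy(x), 4), " bits, I(R;M) = ",
      round(mutual_information(x), 4), " bits\n", sep = "")
  invisible(x)
}

#' Marginal distribution of a joint
#'
#' @param j a [joint_distribution()].
#' @param which `"R"` (row sums) or `"M"` (column sums).
#' @return a [finite_distribution()].
#' @export
marginal <- function(j, which = c("R", "M")) {
  stopifnot(inherits(j, "joint_distribution"))
  which <- match.arg(which)
  if (which == "R") finite_distribution(j$r_outcomes, rowSums(j$probs))
  else finite_distribution(j$m_outcomes, colSums(j$probs))
}

#' Shannon entropy in bits
#'
#' `entropy()` computes the Shannon entropy \eqn{H = -\sum_i p_i \log_2 p_i}
#' with the \eqn{0 \log 0 = 0} convention. For distributions estimated from
#' data ([empirical_joint()]) the Miller-Madow bias correction is available
#' via `correction = "miller_madow"`.
#'
#' @param x a [finite_distribution()], [joint_distribution()] (entropy of the
#'   flattened joint) or a bare numeric probability vector.
#' @param correction `"none"` (plug-in, default) or `"miller_madow"`; the
#'   latter requires the object to carry an `n_obs` attribute (set by
#'   [empirical_joint()]).
#' @param ... unused.
#' @return entropy in bits, in `[0, log2(n outcomes)]`.
#' @export
entropy <- function(x, ...) UseMethod("entropy")

entropy_with_correction <- function(p, correction, n_obs) {
  h <- shannon_bits(p)
  if (correction == "miller_madow") {
    if (is.null(n_obs))
      stopf("miller_madow correction needs an empirical distribution (n_obs attribute)")
    h <- mm_adjust(h, sum(p > 0), n_obs)
  }
  h
}

#' @rdname entropy
#' @export
entropy.finite_distribution <- function(x, correction = c("none", "miller_madow"), ...) {
  entropy_with_correction(x$probs, match.arg(correction), attr(x, "n_obs"))
}

#' @rdname entropy
#' @export
entropy.joint_distribution <- function(x, correction = c("none", "miller_madow"), ...) {
  entropy_with_correction(as.vector(x$probs), match.arg(correction), attr(x, "n_obs"))
}

#' @rdname entropy
#' @export
entropy.numeric <- function(x, ...) {
  entropy(finite_distribution(paste0("o", seq_along(x)), x))
}

#' Conditional entropy H(X|Y) or a per-realization slice H(X|Y=y)
#'
#' With `given = NULL`, returns the averaged conditional entropy
#' \eqn{H(X|Y) = \sum_y p(y) H(X|Y=y) = H(X,Y) - H(Y)}, which never exceeds
#' the marginal entropy \eqn{H(X)}. With `given` set to a conditioning
#' outcome, returns the entropy of the corresponding slice; a *specific*
#' realization may well exceed the unconditional entropy — the effect behind
#' branch-point disorientation at unusually uniform option sets.
#'
#' @param j a [joint_distribution()].
#' @param direction `"R_given_M"` for H(R|M) (the surprise channel) or
#'   `"M_given_R"` for H(M|R) (the uncertainty channel).
#' @param given optional label of the conditioning outcome (an M outcome for
#'   `"R_given_M"`, an R outcome for `"M_given_R"`).
#' @inheritParams entropy
#' @return bits.
#' @export
conditional_entropy <- function(j, direction = c("R_given_M", "M_given_R"),
                                given = NULL,
                                correction = c("none", "miller_madow")) {
  stopifnot(inherits(j, "joint_distribution"))
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  if (is.null(given)) {
    y <- if (direction == "R_given_M") marginal(j, "M") else marginal(j, "R")
    return(entropy(j, correction = correction) -
             entropy_with_correction(y$probs, correction, attr(j, "n_obs")))
  }
  given <- as.character(given)
  slice <- if (direction == "R_given_M") {
    if (!given %in% j$m_outcomes) stopf("unknown conditioning outcome '%s'", given)
    j$probs[, given]
  } else {
    if (!given %in% j$r_outcomes) stopf("unknown conditioning outcome '%s'", given)
    j$probs[given, ]
  }
  tot <- sum(slice)
  if (tot <= 0) stopf("conditioning outcome '%s' has probability zero", given)
  shannon_bits(slice / tot)
}

#' Joint entropy H(R,M)
#'
#' @inheritParams conditional_entropy
#' @return bits; satisfies `max(H(R), H(M)) <= H(R,M) <= H(R) + H(M)`.
#' @export
joint_entropy <- function(j, correction = c("none", "miller_madow")) {
  stopifnot(inherits(j, "joint_distribution"))
  entropy(j, correction = match.arg(correction))
}

#' Mutual information I(R;M)
#'
#' The therapy objective: `I = H(R) + H(M) - H(R,M)`, symmetric and
#' non-negative (up to floating point for plug-in estimates).
#'
#' @inheritParams conditional_entropy
#' @return bits.
#' @export
mutual_information <- function(j, correction = c("none", "miller_madow")) {
  stopifnot(inherits(j, "joint_distribution"))
  correction <- match.arg(correction)
  n <- attr(j, "n_obs")
  entropy_with_correction(rowSums(j$probs), correction, n) +
    entropy_with_correction(colSums(j$probs), correction, n) -
    entropy(j, correction = correction)
}

#' Entropy distance (variation of information)
#'
#' The distance `D_H(R,M) = H(R|M) + H(M|R)` between two random variables: a
#' metric that is zero iff each variable determines the other, and equal to
#' `H(R) + H(M)` under independence. Identically `H(R,M) - I(R;M)`.
#'
#' @inheritParams conditional_entropy
#' @return bits, non-negative.
#' @export
entropy_distance <- function(j, correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  conditional_entropy(j, "R_given_M", correction = correction) +
    conditional_entropy(j, "M_given_R", correction = correction)
}

#' Plug-in joint distribution from paired observations
#'
#' Builds the maximum-likelihood (co-occurrence count) joint of two observed
#' symbol streams; the outcome sets are the observed supports. The result
#' carries an `n_obs` attribute so entropy-type functions can apply the
#' Miller-Madow correction when asked.
#'
#' @param r,m equal-length vectors of observed symbols (coerced to character).
#' @return a [joint_distribution()] with attribute `n_obs`.
#' @export
empirical_joint <- function(r, m) {
  r <- as.character(r); m <- as.character(m)
  if (length(r) == 0L) stopf("empty observation sequence")
  if (length(r) != length(m)) stopf("r and m must have equal length")
  tab <- table(factor(r, levels = unique(r)), factor(m, levels = unique(m)))
  j <- joint_distribution(rownames(tab), colnames(tab),
                          unclass(tab) / length(r))
  attr(j, "n_obs") <- length(r)
  j
}

## ---- serialization (plain JSON) -------------------------------------------

#' Serialize / deserialize distribution objects as JSON
#'
#' Plain structured-text round trip for [finite_distribution()] and
#' [joint_distribution()] objects.
#'
#' @param x a distribution object.
#' @return `dist_to_json()` a JSON string; `dist_from_json()` the
#'   reconstructed object.
#' @export
dist_to_json <- function(x) {
  if (inherits(x, "finite_distribution")) {
    jsonlite::toJSON(list(type = "finite", outcomes = x$outcomes, probs = x$probs),
                     digits = NA, auto_unbox = TRUE)
  } else if (inherits(x, "joint_distribution")) {
    jsonlite::toJSON(list(type = "joint", r_outcomes = x$r_outcomes,
                          m_outcomes = x$m_outcomes,
                          probs = unname(x$probs)), digits = NA, auto_unbox = TRUE)
  } else stopf("not a distribution object")
}

#' @rdname dist_to_json
#' @param txt a JSON string produced by `dist_to_json()`.
#' @export
dist_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt)
  if (identical(doc$type, "finite")) {
    finite_distribution(doc$outcomes, doc$probs)
  } else if (identical(doc$type, "joint")) {
    joint_distribution(doc$r_outcomes, doc$m_outcomes, doc$probs)
  } else stopf("unrecognized distribution document")
}
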