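#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Shannon entropy in bits of an (already normalized) probability vector,
## with the 0*log(0) = 0 convention.
shannon_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

## sample() treats a length-1 numeric x as 1:x; this wrapper never does.
resample <- function(x, size = 1L, prob = NULL) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size = size, replace = TRUE, prob = prob)
}

## Miller-Madow bias adjustment for a plug-in entropy estimate (bits):
## add (k_observed - 1) / (2 n) * log2(e).
mm_adjust <- function(h, k_obs, n_obs) {
  h + (k_obs - 1) / (2 * n_obs) * log2(exp(1))
}

## Stable md5 of an R object, via its canonical JSON rendering (no digest
## dependency in this stack; tools::md5sum works on files).
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, digits = 10, auto_unbox = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

## Run expr under a private RNG stream; `state` is NULL (seed from `seed`)
## or a saved .Random.seed. Returns list(value, state) and restores the
## caller's RNG.
with_rng_stream <- function(state, seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
  value <- force(expr)
  new_state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv()) else rm(".Random.seed", envir = globalenv())
  list(value = value, state = new_state)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
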