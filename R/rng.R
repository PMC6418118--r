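# Seed plumbing: every stochastic entry point takes one integer seed and
# derives independent sub-seeds for its internal stages, so that runs are
# bit-reproducible and sub-streams (schedule vs observer, cohort vs
# permutations) do not interact.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Mixes the master seed with a string tag (and an optional index) through a
#' small multiplicative hash, returning an integer in `[0, 2^31 - 2]` suitable
#' for `set.seed()`. Distinct tags give effectively independent streams.
#'
#' @param seed Integer master seed.
#' @param tag Character stage label, e.g. `"schedule"` or `"observer"`.
#' @param index Optional non-negative integer (e.g. replicate number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m + 1) # avoid the zero fixed point
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  h <- (h * 69621 + as.numeric(index) * 1013904223) %% m
  # a final scramble pass so adjacent indices decorrelate
  h <- (h * 48271) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
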