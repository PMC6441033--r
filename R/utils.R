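#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' One master seed streams to named sub-generators so that each simulated
#' dataset (contact map, peaks, FRET events, ...) draws from an independent,
#' reproducible stream. The mapping is a small deterministic hash of the
#' stream name folded into the master seed, kept within the 32-bit integer
#' range accepted by [set.seed()].
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return An integer seed.
#' @export
sub_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  bytes <- utf8ToInt(name)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(master)) * 69069 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
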