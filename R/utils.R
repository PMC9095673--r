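## Internal helpers: typed conditions and per-stage RNG seed derivation.

stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("degronon_input_error", "degronon_error")))
}

stopConfig <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("degronon_config_error", "degronon_error")))
}

stopDependency <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("degronon_dependency_error", "degronon_error")))
}

stopInternal <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("degronon_internal_error", "degronon_error")))
}

## One RNG stream per generator operation: each operation seeds with a
## distinct affine image of the master seed, so adding a generator never
## perturbs another's output. Offsets are fixed, documented constants.
.streamOffsets <- c(
  substrates = 101L, interactions = 211L, ups = 223L, go = 307L,
  abundance = 401L, network = 503L, coexpr = 509L, motifs = 601L,
  pipeline = 701L, randomize = 809L
)

withStream <- function(seed, stream, expr) {
  off <- .streamOffsets[[stream]]
  if (is.null(off)) stopInternal("unknown RNG stream '%s'", stream)
  seed <- (as.integer(seed) %% 1000000L) * 1000L + off
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic alphabetic protein id helpers
aaAlphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
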