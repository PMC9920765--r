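# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Combine a user seed with stream identifiers into a derived seed < 2^31.
# Multiplicative hashing keeps distinct (seed, ids) streams well separated.
derive_seed <- function(seed, ...) {
  ids <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (v in ids) h <- (h * 1000003 + (v %% 2147483647)) %% 2147483647
  as.integer(h %% 2000000000) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 &&
  x == round(x)
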