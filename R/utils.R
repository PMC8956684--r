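# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Deterministically derive a sub-seed from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.double(seed)) * 7919 + abs(as.double(offset)) * 104729) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

split_features <- function(x) strsplit(x, "|", fixed = TRUE)

join_features <- function(x) paste(x, collapse = "|")

feature_key <- function(x) paste(sort(x), collapse = "|")
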