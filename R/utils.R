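# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial rolling hash); used to fan a master
# seed out into independent substreams keyed by component or drug id, so
# regenerating one artifact never perturbs the stream of another.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 31 + cp) %% 2147483647
  h
}

#' Derive a reproducible substream seed from a master seed and a key
#'
#' @param seed Master integer seed.
#' @param key Character label of the substream (e.g. a drug id or fixture
#'   component name).
#' @return An integer in `[1, 2^31 - 2]`, a pure function of `(seed, key)`.
#' @export
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stable_hash(key)) %%
    2147483646 + 1)
}

# Uppercase, whitespace-stripped gene symbols.
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
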