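# Seed management: one root seed fans out to deterministic substreams so each
# subject/epoch/channel draws from its own stream regardless of evaluation
# order. Substream seeds are derived with an integer hash kept inside the
# 32-bit range R requires of set.seed().

#' @keywords internal
substream_seed <- function(root, ...) {
  keys <- c(...)
  h <- as.double(root %% 2147483647L)
  for (k in keys) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    # 32-bit style mixing in double arithmetic (exact below 2^53)
    h <- (h * 69069 + kv * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr with a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
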