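# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", s), NULL),
         function(x) paste(rev(x), collapse = ""), character(1))
}

substr0 <- function(s, start, end) {
  # 0-based half-open substring
  if (end <= start) return("")
  substr(s, start + 1, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
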