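# Deterministic seed derivation: a Lehmer-style mixing of a master seed with
# an arbitrary sequence of integer/string tokens, so any single fold, repeat
# or grid cell is reproducible in isolation. Multiplier 48271 keeps products
# within exact double-precision integer range; results lie in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (tok in list(...)) {
    if (is.character(tok)) {
      for (ch in utf8ToInt(paste(tok, collapse = "\r"))) {
        h <- (h * 48271 + ch) %% m
      }
    } else {
      for (v in as.numeric(tok)) h <- (h * 48271 + (v %% m)) %% m
    }
    h <- (h * 48271 + 1) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
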