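# run code under a fixed seed without disturbing the caller's random stream
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# deterministic small-integer hash of a logical genome (for per-genome seeds)
genome_hash <- function(bits) {
  h <- 0
  for (chunk in split(as.integer(bits),
                      ceiling(seq_along(bits) / 16L))) {
    h <- (h * 31 + sum(chunk * 2^(seq_along(chunk) - 1L))) %% 2147483629
  }
  as.integer(h)
}
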