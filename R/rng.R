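# Seed handling: one user-facing seed is expanded into independent per-stage
# streams so that, e.g., enlarging the forest does not perturb the synthetic
# cohort. Streams are derived by hashing (seed, label) into [0, 2^31).

derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}
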