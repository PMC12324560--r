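#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic named substream: one master seed fans out to independent
# component seeds (cohort, sc, ts, targets, splits, ...). Kept < 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 100000
  as.integer((abs(as.numeric(seed)) * 10007 + h * 131 + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the undesirable length-1 scalar behaviour
sample_vec <- function(x, ...) x[sample.int(length(x), ...)]
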