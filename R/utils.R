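# Internal helpers: seed derivation and argument checks.

# Deterministically mix a master seed with a label and an integer into a
# 31-bit child seed, so that every (algorithm, k, repeat) cell of an
# experiment gets an independent, reproducible RNG stream.  Pure integer
# arithmetic on doubles below 2^53, reduced mod 2^31 - 1.
derive_seed <- function(master_seed, label = "", n = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(master_seed) %% m)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 131 + (as.numeric(n) %% m)) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
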