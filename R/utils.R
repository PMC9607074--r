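# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation code never perturbs the
# global stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Pearson correlation that tolerates zero-variance inputs: returns 0 with a
# message instead of NA (a filtered signal with no variance carries no
# evidence for any class).
safe_cor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("zero-variance signal in correlation; score set to 0")
    return(0)
  }
  stats::cor(x, y)
}

# md5 of an arbitrary R object via canonical serialization (provenance hash
# for on-disk containers).
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 1
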