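# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards. A NULL seed leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a parent seed; keeps results below
# .Machine$integer.max so they remain valid 32-bit seeds.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647L)
}

.assertScalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (x < min || x > max)
    stop(sprintf("'%s' must lie in [%g, %g], got %g", name, min, max, x))
  invisible(x)
}

.assertCount <- function(x, name, min = 0) {
  .assertScalar(x, name, min = min)
  if (x != round(x)) stop(sprintf("'%s' must be an integer count", name))
  invisible(as.integer(x))
}
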