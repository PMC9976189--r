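# Internal helpers.

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards.  Keeps every stochastic step reproducible
# without clobbering the user's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (divisor N); `type = "sample"` gives the
# usual divisor N-1.
popSd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 1L) stop("need at least one observation")
  if (type == "sample") {
    if (n < 2L) stop("sample SD needs at least two observations")
    return(stats::sd(x))
  }
  sqrt(mean((x - mean(x))^2))
}

# Derive a sub-seed < 2^31 from a base seed and a stage offset.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * offset) %% 2147483647)
}
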