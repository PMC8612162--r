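# Internal helpers.

# Evaluate an expression under a temporary RNG state. With a NULL seed the
# expression runs against the ambient RNG; with an integer seed the global
# RNG is seeded, and its previous state restored afterwards, so seeded
# package functions never perturb a caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
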