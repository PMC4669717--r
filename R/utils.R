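# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic code in the package funnels through this so that
# results are pure functions of their seed arguments.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Child-seed scheme: component seeds are derived from one base seed by fixed
# offsets so that cohorts, the compendium and the permutation null draw from
# independent, reproducible streams. Offsets stay far below 2^31.
child_seed <- function(seed, component = c("cohort", "compendium", "query"),
                       index = 0L) {
  component <- match.arg(component)
  offset <- c(cohort = 100L, compendium = 500L, query = 600L)
  (as.integer(seed) %% 1000000L) * 1000L + offset[[component]] +
    as.integer(index)
}
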