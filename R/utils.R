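# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not perturb the
# session RNG stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stable gene-wise ordering used across outputs
.order_ids <- function(x) x[order(x)]
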