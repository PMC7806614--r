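# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-realization child seeds from a master seed; values stay
# below 2^31 so they are valid R integer seeds.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483629)
}

# Group sums over possibly-empty groups 1..n: zero-padding guarantees every
# group appears, and rowsum() returns groups in sorted order.
group_sums <- function(x, index, n) {
  as.numeric(rowsum(c(x, numeric(n)), c(index, seq_len(n))))
}
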