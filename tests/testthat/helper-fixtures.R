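# Tiny hand-checkable networks ------------------------------------------------

# n agents all sharing one source
star_net <- function(n) bipartite_network(cbind(seq_len(n), rep(1L, n)))

# one agent on two sources
fork_net <- function() bipartite_network(cbind(c(1L, 1L), c(1L, 2L)))

# a1 on {s1, s2}, a2 only on s2 (the boundary-pinning example)
pin_net <- function() bipartite_network(cbind(c(1L, 1L, 2L), c(1L, 2L, 2L)))

# random feasible extraction state
random_state <- function(net, scale = 1) stats::runif(net$E, 0, scale)

# a batch of random study-style networks cycling through the 9 kind combos
random_networks <- function(n, M = 20L, N = 20L, mean_deg = 4, seed = 1L) {
  combos <- expand.grid(s = c("D", "N", "PL"), a = c("U", "R", "SF"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(n), function(i) {
    kk <- combos[((i - 1L) %% nrow(combos)) + 1L, ]
    cprgame:::with_seed(cprgame:::child_seed(seed, i),
                        generate_network(kk$s, kk$a, M = M, N = N,
                                         mean_m = mean_deg, mean_n = mean_deg))
  })
}

# equal-quality state: beta(s) * pressure(s) constant within each component,
# built by splitting each source's target pressure equally among its users
equal_quality_state <- function(net, params, level = 0.3) {
  beta <- resolve_beta(net, params)
  target <- level / beta  # pressure so that beta * pressure == level
  per_edge <- target[net$edges[, 2]] / net$source_deg[net$edges[, 2]]
  per_edge
}

# Study-condition ensembles (M = N = 50, mean degrees 5), generated once per
# test run and shared across acceptance blocks.
study_cache <- new.env(parent = emptyenv())

study_labels <- function() {
  combos <- expand.grid(s = c("D", "N", "PL"), a = c("U", "R", "SF"),
                        stringsAsFactors = FALSE)
  paste0(combos$s, "-", combos$a)
}

get_study_ensembles <- function(n_realizations = 100L, seed = 20260923L) {
  key <- paste0("ens_", n_realizations, "_", seed)
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  combos <- expand.grid(s = c("D", "N", "PL"), a = c("U", "R", "SF"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    spec <- ensemble_spec(combos$s[i], combos$a[i],
                          n_realizations = n_realizations,
                          seed = cprgame:::child_seed(seed, i))
    list(spec = spec, label = spec$label,
         networks = generate_ensemble(spec),
         source_dist = combos$s[i], agent_dist = combos$a[i])
  })
  names(out) <- vapply(out, `[[`, "", "label")
  study_cache[[key]] <- out
  out
}
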