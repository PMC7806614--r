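#' Parameters of the CPR extraction game
#'
#' Each source returns a benefit `b(s) = alpha - beta(s) * pressure(s)` per
#' unit of extraction effort, and an agent's payoff is
#' `f(a) = sum_s q(a,s) b(s) - gamma/2 * total(a)^2`. Two capacity scenarios
#' resolve the per-source degradation slope: `"uniform"` uses the constant
#' `beta`; `"degree_proportional"` uses `beta(s) = beta0 * <n> / n(s)`, so
#' quality degrades with the pressure per user.
#'
#' @param alpha benefit per unit effort on a pristine source (> 0).
#' @param gamma diminishing-marginal-utility coefficient (>= 0).
#' @param scenario `"uniform"` or `"degree_proportional"`.
#' @param beta uniform-scenario slope (> 0).
#' @param beta0 degree-proportional base slope (> 0).
#' @return object of class `game_params`.
#' @export
game_params <- function(alpha = 1, gamma = 0,
                        scenario = c("uniform", "degree_proportional"),
                        beta = 1, beta0 = 1) {
  scenario <- match.arg(scenario)
  if (alpha <= 0) stop("`alpha` must be positive")
  if (gamma < 0) stop("`gamma` must be nonnegative")
  if (beta <= 0 || beta0 <= 0) stop("degradation slopes must be positive")
  structure(list(alpha = alpha, gamma = gamma, scenario = scenario,
                 beta = beta, beta0 = beta0),
            class = "game_params")
}

#' Resolve the per-source degradation slopes
#'
#' @param net a [bipartite_network()].
#' @param params a [game_params()].
#' @return numeric vector `beta(s)` of length `net$N`, all positive.
#' @export
resolve_beta <- function(net, params) {
  switch(params$scenario,
         uniform = rep(params$beta, net$N),
         degree_proportional = params$beta0 * mean(net$source_deg) / net$source_deg)
}

check_state <- function(q, net) {
  q <- as.numeric(q)
  if (length(q) != net$E) stop("state must have one effort per network edge")
  if (anyNA(q) || any(q < 0)) stop("extraction efforts must be nonnegative")
  q
}

#' Aggregates of an extraction state
#'
#' `source_pressure()` returns the column sums (total effort exerted on each
#' source); `agent_load()` the row sums (each agent's total effort). States
#' are plain numeric vectors aligned with `net$edges`.
#'
#' @param q numeric vector of edge efforts aligned with `net$edges`.
#' @param net a [bipartite_network()].
#' @return numeric vector of length `net$N` (resp. `net$M`).
#' @export
source_pressure <- function(q, net) {
  group_sums(check_state(q, net), net$edges[, 2], net$N)
}

#' @rdname source_pressure
#' @export
agent_load <- function(q, net) {
  group_sums(check_state(q, net), net$edges[, 1], net$M)
}

#' Source qualities of a state
#'
#' `b(s) = alpha - beta(s) * pressure(s)`. Quality has no floor: negative
#' values represent over-exploitation and are propagated as is.
#'
#' @inheritParams source_pressure
#' @param params a [game_params()].
#' @return numeric vector of qualities, length `net$N`.
#' @export
source_quality <- function(q, net, params) {
  params$alpha - resolve_beta(net, params) * source_pressure(q, net)
}

#' Agent payoffs of a state
#'
#' @inheritParams source_quality
#' @return numeric vector `f(a)` of length `net$M`.
#' @export
agent_payoffs <- function(q, net, params) {
  q <- check_state(q, net)
  b <- source_quality(q, net, params)
  benefit <- group_sums(q * b[net$edges[, 2]], net$edges[, 1], net$M)
  benefit - params$gamma / 2 * agent_load(q, net)^2
}

#' Collective wealth of a state
#'
#' With costs included this is `F = sum_a f(a)`; without costs it is
#' `F0 = sum_s pressure(s) * b(s)`, the convention used when comparing states
#' reached by reallocation (quadratic costs are invariant under reallocation).
#'
#' @inheritParams source_quality
#' @param include_costs include the quadratic cost terms? Default `TRUE`.
#' @return a single number.
#' @export
collective_wealth <- function(q, net, params, include_costs = TRUE) {
  if (include_costs) sum(agent_payoffs(q, net, params))
  else sum(source_pressure(q, net) * source_quality(q, net, params))
}

#' Gini index of a payoff vector
#'
#' `G = sum_ij |v_i - v_j| / (2 M sum_i v_i)`, in `[0, 1]` for nonnegative
#' values. Negative entries trigger a warning (the index is still computed);
#' a nonpositive total is an error because the index is undefined there.
#'
#' @param values non-empty numeric vector.
#' @return Gini index.
#' @export
gini <- function(values) {
  if (!length(values) || anyNA(values)) stop("`values` must be non-empty and free of NA")
  if (sum(values) <= 0) stop("Gini index undefined for a nonpositive total")
  if (any(values < 0)) warning("negative values supplied to gini(); index may exceed [0, 1]")
  v <- sort(values)
  n <- length(v)
  2 * sum(seq_len(n) * v) / (n * sum(v)) - (n + 1) / n
}

# Gini over a discrete distribution of class values with masses `weights`.
gini_weighted <- function(values, weights) {
  mu <- sum(values * weights)
  if (mu <= 0) stop("Gini index undefined for a nonpositive mean")
  sum(outer(weights, weights) * abs(outer(values, values, "-"))) / (2 * mu)
}

#' Connected components of a bipartite network
#'
#' @param net a [bipartite_network()].
#' @return list with `n_components`, `agent_comp` (length `M`) and
#'   `source_comp` (length `N`) membership vectors.
#' @export
network_components <- function(net) {
  g <- igraph::graph_from_edgelist(cbind(net$edges[, 1], net$M + net$edges[, 2]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  list(n_components = comp$no,
       agent_comp = comp$membership[seq_len(net$M)],
       source_comp = comp$membership[net$M + seq_len(net$N)])
}

#' Steady-state quality reached by reallocation
#'
#' Reallocation conserves each agent's total effort, so within every
#' connected component the total pressure is conserved and the common final
#' quality is `b_f = alpha - sum_s pressure(s) / sum_s beta(s)^-1`, averages
#' taken within the component.
#'
#' @inheritParams source_quality
#' @return numeric vector with one `b_f` per connected component, with the
#'   source membership vector attached as attribute `source_comp`.
#' @export
steady_quality <- function(q, net, params) {
  comp <- network_components(net)
  beta <- resolve_beta(net, params)
  pr <- source_pressure(q, net)
  ids <- seq_len(comp$n_components)
  bf <- vapply(ids, function(cc) {
    s <- comp$source_comp == cc
    params$alpha - sum(pr[s]) / sum(1 / beta[s])
  }, 0.0)
  attr(bf, "source_comp") <- comp$source_comp
  bf
}

#' Cost-free collective wealth of the reallocation steady state
#'
#' `F_f = sum_components Q_c * b_f(c)`: each component's conserved total
#' pressure times its common final quality. By the Cauchy-Schwarz argument
#' this is at least the initial cost-free wealth `F0`, with equality exactly
#' when `beta(s) * pressure(s)` is constant within every component.
#'
#' @inheritParams source_quality
#' @return a single number.
#' @export
steady_wealth <- function(q, net, params) {
  bf <- steady_quality(q, net, params)
  pr <- source_pressure(q, net)
  comp <- attr(bf, "source_comp")
  sum(vapply(seq_along(bf), function(cc) sum(pr[comp == cc]) * bf[cc], 0.0))
}
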