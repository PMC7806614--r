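edge_arrays <- function(net, params) {
  list(ae = net$edges[, 1] - 1L, se = net$edges[, 2] - 1L,
       astart = c(0L, cumsum(net$agent_deg)),
       beta = resolve_beta(net, params))
}

solver_report <- function(state, objective, kkt_residual, iterations, converged) {
  structure(list(state = state, objective = objective,
                 kkt_residual = kkt_residual, iterations = iterations,
                 converged = converged),
            class = "solver_report")
}

#' @export
print.solver_report <- function(x, ...) {
  cat(sprintf("solver_report: objective %.6g, KKT residual %.3g, %d iterations, %s\n",
              x$objective, x$kkt_residual, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Exact potential whose maximizer over the nonnegative orthant is the Nash
# state: P = sum_s(alpha q> - beta q>^2/2 - beta sum_a q^2/2) - gamma/2 sum_a q<^2.
game_potential <- function(q, net, params) {
  beta <- resolve_beta(net, params)
  pr <- source_pressure(q, net)
  sum(params$alpha * pr - beta * pr^2 / 2) -
    sum(beta[net$edges[, 2]] * q^2) / 2 -
    params$gamma / 2 * sum(agent_load(q, net)^2)
}

#' Nash equilibrium of the extraction game
#'
#' The game admits the exact concave potential maximized here by projected
#' cyclic best response; strict concavity makes the equilibrium unique. The
#' returned state satisfies, on every edge, the complementarity conditions
#' `q >= 0`, `alpha - beta(s) pressure(s) - beta(s) q - gamma load(a) <= 0`,
#' with a zero product.
#'
#' @param net a [bipartite_network()].
#' @param params a [game_params()].
#' @param q0 optional starting state (defaults to all zeros).
#' @param tol KKT residual tolerance.
#' @param maxit sweep budget.
#' @return a `solver_report` with fields `state`, `objective` (potential
#'   value), `kkt_residual`, `iterations`, `converged`.
#' @export
nash_equilibrium <- function(net, params, q0 = NULL, tol = 1e-9, maxit = 100000L) {
  ea <- edge_arrays(net, params)
  q0 <- if (is.null(q0)) numeric(net$E) else check_state(q0, net)
  out <- cpp_nash_solve(ea$ae, ea$se, ea$beta, params$alpha, params$gamma,
                        net$M, net$N, q0, tol, as.integer(maxit))
  solver_report(out$q, game_potential(out$q, net, params),
                out$residual, out$iterations, out$converged)
}

#' Complementarity residual of the Nash contract
#'
#' @inheritParams nash_equilibrium
#' @param q state to check.
#' @return max over edges of `|min(q, -marginal payoff)|`.
#' @export
nash_residual <- function(q, net, params) {
  ea <- edge_arrays(net, params)
  cpp_nash_residual(ea$ae, ea$se, ea$beta, params$alpha, params$gamma,
                    net$M, net$N, check_state(q, net))
}

#' Pareto efficient extraction state
#'
#' Maximizes collective wealth `F = sum_a f(a)` over the nonnegative orthant
#' (a concave quadratic program). At `gamma = 0` the problem decouples source
#' by source — each source's optimal pressure is `alpha / (2 beta(s))` — and
#' the minimum-Euclidean-norm maximizer (equal split among a source's users)
#' is returned in closed form. For `gamma > 0` projected cyclic coordinate
#' ascent from zero is used; the optimal value `F` is unique.
#'
#' @inheritParams nash_equilibrium
#' @return a `solver_report`; `objective` is the collective wealth.
#' @export
pareto_efficient <- function(net, params, tol = 1e-9, maxit = 100000L) {
  ea <- edge_arrays(net, params)
  if (params$gamma == 0) {
    q <- params$alpha / (2 * ea$beta[net$edges[, 2]] * net$source_deg[net$edges[, 2]])
    return(solver_report(q, collective_wealth(q, net, params), 0, 0L, TRUE))
  }
  out <- cpp_pareto_solve(ea$ae, ea$se, ea$beta, params$alpha, params$gamma,
                          net$M, net$N, numeric(net$E), tol, as.integer(maxit))
  solver_report(out$q, collective_wealth(out$q, net, params),
                out$residual, out$iterations, out$converged)
}

#' Reallocation steady state with conserved agent totals
#'
#' Computes a state with the same per-agent totals as `initial` in which no
#' agent still faces a quality gradient: for every agent `a` and affiliated
#' source `s`, `b(s) <= mu(a)` with equality wherever `q(a,s) > 0`, `mu(a)`
#' being the top quality among the agent's sources. This is the linear
#' complementarity form of the fixed points of myopic reallocation; it is
#' solved by block-coordinate ascent, each block an exact water-filling of
#' one agent's conserved total.
#'
#' @inheritParams nash_equilibrium
#' @param initial starting state whose per-agent totals are conserved.
#' @return a `solver_report`; `objective` is the aggregate surplus
#'   `sum_s (alpha q>(s) - beta(s) q>(s)^2 / 2)` whose constrained maximizer
#'   the steady state is.
#' @export
steady_state <- function(net, params, initial, tol = 1e-9, maxit = 100000L) {
  ea <- edge_arrays(net, params)
  q0 <- check_state(initial, net)
  out <- cpp_steady_solve(ea$ae, ea$se, ea$astart, ea$beta, params$alpha,
                          net$M, net$N, q0, tol, as.integer(maxit))
  pr <- source_pressure(out$q, net)
  solver_report(out$q, sum(params$alpha * pr - ea$beta * pr^2 / 2),
                out$residual, out$iterations, out$converged)
}

#' Steady-state complementarity residual
#'
#' @inheritParams nash_residual
#' @return max over used edges of the gap to the agent's top quality.
#' @export
steady_residual <- function(q, net, params) {
  ea <- edge_arrays(net, params)
  cpp_steady_residual(ea$ae, ea$se, ea$astart, ea$beta, params$alpha,
                      net$N, check_state(q, net))
}

#' Best response of a single agent
#'
#' Maximizes one agent's payoff over its own (unconstrained-total,
#' nonnegative) extraction levels while all other agents hold theirs fixed.
#' Used as an independent optimality check on equilibrium states and to
#' exhibit that reallocation steady states are typically not Nash.
#'
#' @inheritParams nash_residual
#' @param agent agent id (1-based).
#' @return list with `q_agent` (optimal efforts on the agent's edges, in
#'   edge order), `payoff_before`, `payoff_after`, `improvement`.
#' @export
best_response <- function(net, params, q, agent, tol = 1e-13, maxit = 10000L) {
  q <- check_state(q, net)
  beta <- resolve_beta(net, params)
  idx <- which(net$edges[, 1] == agent)
  if (!length(idx)) stop("agent has no edges")
  s <- net$edges[idx, 2]
  pr_other <- source_pressure(q, net)[s] - q[idx]
  payoff_of <- function(qa) {
    sum(qa * (params$alpha - beta[s] * (pr_other + qa))) -
      params$gamma / 2 * sum(qa)^2
  }
  qa <- q[idx]
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_along(qa)) {
      qn <- max(0, (params$alpha - beta[s[j]] * pr_other[j] -
                      params$gamma * (sum(qa) - qa[j])) /
                     (2 * beta[s[j]] + params$gamma))
      delta <- max(delta, abs(qn - qa[j]))
      qa[j] <- qn
    }
    if (delta < tol) break
  }
  f0 <- payoff_of(q[idx])
  f1 <- payoff_of(qa)
  list(q_agent = qa, payoff_before = f0, payoff_after = f1,
       improvement = f1 - f0)
}
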