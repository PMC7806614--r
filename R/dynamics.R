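#' Right-hand side of the myopic reallocation flow
#'
#' `dq(a,s)/dt = k * sum_{s' in S_a} [b(s) - b(s')]
#'             = k * (m(a) b(s) - sum_{s'} b(s'))`.
#' Row sums over each agent's edges are exactly zero, so every agent's total
#' effort is conserved. This is the unprojected interior field; the
#' integrator additionally suppresses outflow from edges at zero.
#'
#' @param q state vector aligned with `net$edges`.
#' @param net a [bipartite_network()].
#' @param params a [game_params()].
#' @param k rate constant (> 0); a pure time scale.
#' @return derivative vector, one entry per edge.
#' @export
reallocation_rhs <- function(q, net, params, k = 1) {
  b <- source_quality(q, net, params)
  be <- b[net$edges[, 2]]
  S <- group_sums(be, net$edges[, 1], net$M)
  k * (net$agent_deg[net$edges[, 1]] * be - S[net$edges[, 1]])
}

#' Integrate the reallocation dynamics
#'
#' Projected explicit Euler: at `q(a,s) = 0` the negative part of the
#' derivative is suppressed and the balancing inflows rescaled so each
#' agent's derivative still sums to zero, and every step is truncated so no
#' edge crosses zero. Convergence is declared when the quality spread — the
#' largest gap, over agents, between the best affiliated quality and the
#' worst quality among sources the agent still uses — falls below `tol`.
#'
#' @param initial nonnegative starting state aligned with `net$edges`.
#' @inheritParams reallocation_rhs
#' @param dt step size; default `0.01 / (k * max(beta) * max(agent degree))`.
#' @param t_max time horizon.
#' @param tol quality-spread convergence threshold.
#' @param record_every record the trace every this many steps.
#' @param max_steps hard step budget.
#' @return object of class `dynamics_trace`: `times`, `quality_spread`,
#'   `wealth_costfree`, `wealth_total`, `final_state`, `converged`,
#'   `convergence_time`, `steps`.
#' @export
integrate_reallocation <- function(initial, net, params, k = 1, dt = NULL,
                                   t_max = 1000, tol = 1e-8,
                                   record_every = 10L, max_steps = 10000000L) {
  if (k <= 0) stop("`k` must be positive")
  ea <- edge_arrays(net, params)
  q0 <- check_state(initial, net)
  if (is.null(dt)) dt <- 0.01 / (k * max(ea$beta) * max(net$agent_deg))
  if (dt <= 0 || tol <= 0) stop("`dt` and `tol` must be positive")
  out <- cpp_integrate(ea$ae, ea$se, ea$astart, ea$beta, params$alpha,
                       params$gamma, k, q0, dt, t_max, tol,
                       as.integer(record_every), as.integer(max_steps))
  structure(list(times = out$times, quality_spread = out$quality_spread,
                 wealth_costfree = out$wealth_costfree,
                 wealth_total = out$wealth_total,
                 final_state = out$q, converged = out$converged,
                 convergence_time = out$convergence_time,
                 steps = out$steps, t_end = out$t_end),
            class = "dynamics_trace")
}

#' @export
print.dynamics_trace <- function(x, ...) {
  cat(sprintf("dynamics_trace: %d steps to t = %.4g, spread %.3g, %s\n",
              x$steps, x$t_end, utils::tail(x$quality_spread, 1),
              if (x$converged) sprintf("converged at t = %.4g", x$convergence_time)
              else "not converged"))
  invisible(x)
}
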