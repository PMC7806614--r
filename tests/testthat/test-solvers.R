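# Independent oracle: synchronous best-response iteration on agent blocks,
# damped for stability; shares no code with the coordinate solver.
best_response_oracle <- function(net, params, iters = 5000, damp = 0.5) {
  beta <- resolve_beta(net, params)
  q <- rep(0.1, net$E)
  for (it in seq_len(iters)) {
    qn <- q
    for (a in seq_len(net$M)) {
      idx <- which(net$edges[, 1] == a)
      br <- best_response(net, params, q, a)
      qn[idx] <- (1 - damp) * q[idx] + damp * br$q_agent
    }
    if (max(abs(qn - q)) < 1e-12) { q <- qn; break }
    q <- qn
  }
  q
}

test_that("single-source stars recover the closed-form equilibrium", {
  for (n in c(1L, 2L, 5L, 10L)) {
    net <- star_net(n)
    for (g in c(0, 0.2, 1)) {
      p <- game_params(gamma = g)
      rep <- nash_equilibrium(net, p)
      expect_true(rep$converged)
      expect_equal(rep$state, rep(1 / (n + 1 + g), n), tolerance = 1e-7)
    }
  }
  # two agents, one shared source, gamma = 0: q = 1/3, b = 1/3, so each agent
  # earns f = q b = 1/9 and the population extracts F = Q b = 2/9
  net <- star_net(2)
  p <- game_params()
  eq <- nash_equilibrium(net, p)
  expect_equal(source_quality(eq$state, net, p), 1 / 3, tolerance = 1e-7)
  expect_equal(agent_payoffs(eq$state, net, p), rep(1 / 9, 2), tolerance = 1e-7)
  expect_equal(collective_wealth(eq$state, net, p), 2 / 9, tolerance = 1e-7)
})

test_that("the equilibrium matches damped best-response iteration", {
  set.seed(41)
  net <- generate_network("N", "R", M = 8, N = 8, mean_m = 3, mean_n = 3)
  for (p in list(game_params(gamma = 0), game_params(gamma = 0.4),
                 game_params(gamma = 0.2, scenario = "degree_proportional"))) {
    eq <- nash_equilibrium(net, p)
    oracle <- best_response_oracle(net, p)
    expect_lt(max(abs(eq$state - oracle)), 1e-7)
  }
})

test_that("the equilibrium is unique across starting points", {
  set.seed(42)
  for (net in random_networks(5, seed = 17)) {
    p <- game_params(gamma = 0.2)
    a <- nash_equilibrium(net, p)
    b <- nash_equilibrium(net, p, q0 = random_state(net, 2))
    expect_lt(max(abs(a$state - b$state)), 1e-7)
    expect_lte(a$kkt_residual, 1e-9)
  }
})

test_that("efficient states maximize wealth with the documented tie-break", {
  p <- game_params()
  # one source, three agents: total pressure 1/2, F = 1/4, equal (min-norm) split
  net <- star_net(3)
  ef <- pareto_efficient(net, p)
  expect_equal(ef$state, rep(1 / 6, 3))
  expect_equal(ef$objective, 0.25)
  # extreme diminishing returns drive extraction to zero
  efg <- pareto_efficient(net, game_params(gamma = 1e6))
  expect_lt(sum(efg$state), 1e-4)
  expect_lt(abs(efg$objective), 1e-4)
  # gamma > 0: KKT contract and superiority over random states and Nash
  set.seed(43)
  for (net in random_networks(4, seed = 19)) {
    pg <- game_params(gamma = 0.3)
    ef <- pareto_efficient(net, pg)
    expect_true(ef$converged)
    expect_lte(ef$kkt_residual, 1e-9)
    expect_gte(ef$objective, collective_wealth(random_state(net), net, pg))
    expect_gte(ef$objective,
               collective_wealth(nash_equilibrium(net, pg)$state, net, pg))
  }
})

test_that("steady states equalize quality over each agent's used sources", {
  p <- game_params()
  ss <- steady_state(fork_net(), p, c(0.6, 0))
  expect_equal(ss$state, c(0.3, 0.3), tolerance = 1e-10)
  expect_equal(source_quality(ss$state, fork_net(), p), c(0.7, 0.7))

  # boundary pinning: a1 cannot equalize because s2 is swamped by a2
  ss2 <- steady_state(pin_net(), p, c(0.05, 0.05, 0.9))
  expect_equal(ss2$state, c(0.1, 0, 0.9), tolerance = 1e-10)
  expect_equal(source_quality(ss2$state, pin_net(), p), c(0.9, 0.1))

  # an interior equal-quality state is a fixed point
  q0 <- c(0.3, 0.3)
  expect_equal(steady_state(fork_net(), p, q0)$state, q0, tolerance = 1e-12)
})

test_that("steady states conserve totals and satisfy complementarity", {
  set.seed(44)
  for (net in random_networks(8, seed = 23)) {
    p <- game_params(gamma = 0.2)
    q0 <- random_state(net)
    ss <- steady_state(net, p, q0)
    expect_true(ss$converged)
    expect_lt(max(abs(agent_load(ss$state, net) - agent_load(q0, net))), 1e-10)
    expect_lte(steady_residual(ss$state, net, p), 1e-9)
    expect_true(all(ss$state >= 0))
  }
})

test_that("reallocation steady states are typically not Nash", {
  # heterogeneous source degrees + costly extraction: some agent can still
  # gain by changing its total, which reallocation forbids
  set.seed(45)
  net <- generate_network("PL", "R", M = 20, N = 20, mean_m = 4, mean_n = 4)
  p <- game_params(gamma = 0.5)
  eq <- nash_equilibrium(net, p)
  ss <- steady_state(net, p, eq$state)
  gains <- vapply(seq_len(net$M), function(a)
    best_response(net, p, ss$state, a)$improvement, 0.0)
  expect_gt(max(gains), 1e-6)
})

test_that("wealth is ordered equilibrium <= steady state <= efficient", {
  set.seed(46)
  for (net in random_networks(6, seed = 29)) {
    for (p in list(game_params(), game_params(gamma = 0.2))) {
      eq <- nash_equilibrium(net, p)
      ss <- steady_state(net, p, eq$state)
      ef <- pareto_efficient(net, p)
      F_eq <- collective_wealth(eq$state, net, p)
      F_ss <- collective_wealth(ss$state, net, p)
      expect_gte(F_ss, F_eq - 1e-9)
      expect_gte(ef$objective, F_ss - 1e-9)
    }
  }
})
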