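test_that("degradation slopes resolve per capacity scenario", {
  net <- star_net(3)  # one source of degree 3
  expect_equal(resolve_beta(net, game_params(beta = 1)), 1)
  expect_equal(resolve_beta(net, game_params(beta = 2.5)), 2.5)

  # degree-proportional: a1 on {s1, s2}, a2 and a3 on s1 only
  net2 <- bipartite_network(cbind(c(1L, 1L, 2L, 3L), c(1L, 2L, 1L, 1L)))
  p <- game_params(scenario = "degree_proportional", beta0 = 1)
  # n = (3, 1), <n> = 2: beta = beta0 * <n> / n
  expect_equal(resolve_beta(net2, p), c(2 / 3, 2))
  # a mean-degree source gets beta0 itself
  reg <- build_bipartite(rep(3L, 6), rep(3L, 6))
  expect_equal(resolve_beta(reg, p), rep(1, 6))
})

test_that("quality and payoffs evaluate the linear-quadratic forms exactly", {
  net <- star_net(1)
  p0 <- game_params(gamma = 0)
  expect_equal(source_quality(0, net, p0), 1)        # pristine source
  expect_equal(source_quality(0.6, net, p0), 0.4)
  expect_equal(agent_payoffs(0.5, net, p0), 0.25)    # 0.5 * 0.5
  p1 <- game_params(gamma = 1)
  expect_equal(agent_payoffs(0.5, net, p1), 0.125)   # 0.25 - 0.5 * 0.25
  expect_equal(agent_payoffs(0, net, p1), 0)
  # quality may go negative under over-exploitation
  expect_equal(source_quality(3, net, p0), -2)
})

test_that("collective wealth follows the with/without-cost conventions", {
  net <- fork_net()
  p <- game_params()
  expect_equal(collective_wealth(c(0.6, 0), net, p, include_costs = FALSE), 0.24)
  expect_equal(collective_wealth(c(0.3, 0.3), net, p, include_costs = FALSE), 0.42)
  expect_equal(collective_wealth(c(0, 0), net, p), 0)
  # with gamma = 0 and no costs the two conventions agree
  expect_equal(collective_wealth(c(0.6, 0), net, p),
               collective_wealth(c(0.6, 0), net, p, include_costs = FALSE))
})

test_that("gini matches hand-computed values and guards its domain", {
  expect_equal(gini(rep(3, 7)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(1, 1, 1, 0)), 0.25)
  expect_error(gini(c(-1, 0.5)), "nonpositive")
  expect_warning(g <- gini(c(-0.1, 1)), "negative")
  expect_true(is.finite(g))
})

test_that("steady-state quality is the harmonic-slope average per component", {
  p <- game_params()
  net <- star_net(1)
  expect_equal(as.numeric(steady_quality(5 / 6, net, p)), 1 / 6)
  expect_equal(as.numeric(steady_quality(0, net, p)), 1)

  # two sources with beta = (1.5, 0.75) via degree-proportional resolution,
  # pressures (0.3, 0.3): b_f = 1 - 0.6 / (1/1.5 + 1/0.75) = 0.7
  net2 <- bipartite_network(cbind(c(1L, 1L, 2L), c(1L, 2L, 2L)))
  pd <- game_params(scenario = "degree_proportional", beta0 = 1)
  expect_equal(resolve_beta(net2, pd), c(1.5, 0.75))
  expect_equal(as.numeric(steady_quality(c(0.3, 0.15, 0.15), net2, pd)), 0.7)

  # disconnected components each get their own b_f
  two <- bipartite_network(cbind(c(1L, 2L), c(1L, 2L)))
  bf <- steady_quality(c(0.2, 0.8), two, p)
  expect_equal(as.numeric(bf), c(0.8, 0.2))
})

test_that("per-effort wealth identity holds to machine precision", {
  set.seed(21)
  p_u <- game_params(gamma = 0.3)
  p_d <- game_params(gamma = 0.3, scenario = "degree_proportional")
  for (net in random_networks(6, seed = 8)) {
    for (p in list(p_u, p_d)) {
      q <- random_state(net)
      pr <- source_pressure(q, net)
      beta <- resolve_beta(net, p)
      F0 <- collective_wealth(q, net, p, include_costs = FALSE)
      Q <- sum(pr)
      expect_equal(F0 / Q, p$alpha - mean(beta * pr^2) / mean(pr), tolerance = 1e-12)
    }
  }
})

test_that("reallocation can only raise cost-free wealth (Cauchy-Schwarz)", {
  set.seed(22)
  p_u <- game_params(gamma = 0)
  p_d <- game_params(scenario = "degree_proportional")
  for (net in random_networks(10, seed = 9)) {
    for (p in list(p_u, p_d)) {
      q <- random_state(net)
      expect_gte(steady_wealth(q, net, p) -
                   collective_wealth(q, net, p, include_costs = FALSE), -1e-12)
      # equality exactly on equal-quality states (beta * pressure constant)
      qe <- equal_quality_state(net, p)
      expect_equal(steady_wealth(qe, net, p),
                   collective_wealth(qe, net, p, include_costs = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("scaling a cost-free state scales wealth per the identity", {
  set.seed(23)
  net <- random_networks(1, seed = 14)[[1]]
  p <- game_params(gamma = 0)
  q <- random_state(net)
  pr <- source_pressure(q, net)
  beta <- resolve_beta(net, p)
  expect_equal(source_pressure(2 * q, net), 2 * pr)
  expect_equal(collective_wealth(2 * q, net, p, include_costs = FALSE),
               sum(2 * pr * (p$alpha - beta * 2 * pr)))
})

test_that("states round-trip losslessly through TSV with a params sidecar", {
  set.seed(15)
  net <- generate_network("N", "R", M = 10, N = 10, mean_m = 3, mean_n = 3)
  q <- random_state(net)
  p <- game_params(gamma = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_state(q, net, path, params = p)
  back <- read_state(path, net)
  expect_identical(as.numeric(back), q)
  expect_equal(attr(back, "params")$gamma, 0.2)
})
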