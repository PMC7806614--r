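# A fixed heterogeneous pair of degree distributions used across blocks.
# Node counts satisfy edge-count consistency: M <m> = 46 * 4.4 = 44 * 4.6 = N <n>.
mixed_dists <- function() {
  degree_distributions(
    P_A = stats::setNames(c(0.3, 0.4, 0.2, 0.1), c(2, 4, 6, 10)),
    P_S = stats::setNames(c(0.25, 0.35, 0.25, 0.15), c(1, 3, 6, 12)),
    M = 46, N = 44)
}

test_that("cost-free pressures have the n/(n+1) closed form", {
  d <- mixed_dists()
  for (p in list(game_params(), game_params(scenario = "degree_proportional"))) {
    qn <- mf_equilibrium_pressures(d, p)
    beta_n <- cprgame:::mf_beta(d$n, p, d$mean_n)
    expect_equal(unname(qn), (p$alpha / beta_n) * d$n / (d$n + 1),
                 tolerance = 1e-12)
  }
})

test_that("scalar reduction and full linear solve agree", {
  d <- mixed_dists()
  for (g in c(0, 0.1, 0.35, 1)) {
    p <- game_params(gamma = g)
    expect_lt(max(abs(mf_equilibrium_pressures(d, p, "reduced") -
                        mf_equilibrium_pressures(d, p, "full"))), 1e-10)
  }
})

test_that("the delta-delta case reproduces every hand-derived value", {
  d <- degree_distributions(stats::setNames(1, "5"), stats::setNames(1, "5"),
                            M = 50, N = 50)
  p <- game_params()
  sol <- mean_field_solution(d, p)
  expect_equal(unname(sol$qn), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(sol$qm), 5 / 6, tolerance = 1e-12)   # 5 * (1 - 5/6)
  expect_equal(as.numeric(sol$qmn), 1 / 6, tolerance = 1e-12)
  expect_equal(sol$F_Eq, 50 * 5 / 36, tolerance = 1e-12)
  expect_equal(sol$F_Ef, 12.5)
  expect_equal(sol$F_Eq / sol$F_Ef, 5 / 9, tolerance = 1e-12)
  expect_equal(sol$G_Eq, 0)                                # identical agents
  expect_equal(unname(sol$delta_f), 0)                     # delta sources: no shift
  # mean field is exact on the regular network it describes
  net <- build_bipartite(rep(5L, 50), rep(5L, 50))
  eq <- nash_equilibrium(net, p)
  expect_equal(source_pressure(eq$state, net), rep(5 / 6, 50), tolerance = 1e-8)
})

test_that("closures hang together: edge balance and aggregation identities", {
  d <- mixed_dists()
  for (g in c(0, 0.2, 0.7)) {
    p <- game_params(gamma = g)
    qn <- mf_equilibrium_pressures(d, p)
    qm <- mf_agent_totals(d, p, qn)
    qmn <- mf_edge_extractions(d, p, qn, qm)
    w <- d$P_S * d$n / d$mean_n
    # each agent class's edges add up to its total
    agg <- as.numeric(qmn %*% w) * d$m
    expect_lt(max(abs(agg - qm)), 1e-10)
    # total extraction counted from agents equals that counted from sources
    expect_lt(abs(d$M * sum(d$P_A * qm) - d$N * sum(d$P_S * qn)), 1e-10)
  }
})

test_that("infinite marginal cost shuts extraction down", {
  d <- mixed_dists()
  p <- game_params(gamma = 1e8)
  qn <- mf_equilibrium_pressures(d, p)
  qm <- mf_agent_totals(d, p, qn)
  expect_lt(max(qm), 1e-6)
})

test_that("payoff shifts: proportional sharing at zero cost, both forms kept", {
  d <- mixed_dists()
  p0 <- game_params()
  sh0 <- mf_payoff_shifts(d, p0, mf_equilibrium_pressures(d, p0),
                          mf_agent_totals(d, p0, mf_equilibrium_pressures(d, p0)))
  # gamma = 0: gains are shared in proportion to degree, and the printed and
  # first-principles evaluations coincide
  per_edge <- sh0$derived / d$m
  expect_lt(diff(range(per_edge)), 1e-12)
  expect_gt(per_edge[1], 0)
  expect_lt(sh0$discrepancy, 1e-12)

  # gamma > 0: per-degree shifts decrease with degree; the printed second
  # bracket deviates from the first-principles value and both are reported
  p2 <- game_params(gamma = 0.2)
  qn <- mf_equilibrium_pressures(d, p2)
  qm <- mf_agent_totals(d, p2, qn)
  sh2 <- mf_payoff_shifts(d, p2, qn, qm)
  expect_true(all(diff(sh2$derived / d$m) < 0))
  expect_true(is.finite(sh2$discrepancy))
})

test_that("gamma sweeps show the documented equality and efficiency patterns", {
  d <- mixed_dists()
  sw <- gamma_sweep(d, game_params(), seq(0, 1, by = 0.05))
  expect_equal(sw$gini_reduction[sw$gamma == 0], 0, tolerance = 1e-12)
  expect_true(all(sw$gini_reduction[sw$gamma > 0.05] > 0))
  # equilibrium efficiency rises with gamma while the reallocation gain fades
  expect_true(all(diff(sw$eff_ratio) > 0))
  expect_lt(sw$realloc_gain[sw$gamma == 1], sw$realloc_gain[sw$gamma == 0])

  # a delta source distribution predicts no reallocation gain at any gamma
  dd <- degree_distributions(stats::setNames(c(0.5, 0.5), c(3, 7)),
                             stats::setNames(1, "5"), M = 50, N = 50)
  swd <- gamma_sweep(dd, game_params(), c(0, 0.2, 0.6))
  expect_equal(swd$realloc_gain, rep(0, 3), tolerance = 1e-12)
  expect_equal(swd$gini_reduction, rep(0, 3), tolerance = 1e-12)
})

test_that("source heterogeneity orders the predicted reallocation gain", {
  # synthetic D / N-like / PL-like source distributions with a common mean
  dD <- stats::setNames(1, "5")
  dN <- stats::setNames(c(0.1, 0.2, 0.4, 0.2, 0.1), c(3, 4, 5, 6, 7))
  plm <- cprgame:::power_law_pmf(5, 25)  # exponent tuned so the mean is 5
  dPL <- stats::setNames(plm$p, plm$d)
  agent <- stats::setNames(1, "5")
  gain <- vapply(list(dD, dN, dPL), function(ps) {
    di <- degree_distributions(agent, ps, M = 50, N = 50)
    gamma_sweep(di, game_params(), 0)$realloc_gain
  }, 0.0)
  expect_equal(gain[1], 0, tolerance = 1e-12)
  expect_gt(gain[2], gain[1])
  expect_gt(gain[3], gain[2])
})
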