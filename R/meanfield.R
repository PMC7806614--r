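# Degree-indexed slopes beta_n for the two capacity scenarios.
mf_beta <- function(n, params, mean_n) {
  switch(params$scenario,
         uniform = rep(params$beta, length(n)),
         degree_proportional = params$beta0 * mean_n / n)
}

# Shared edge-weighted moments of the self-consistency system. With
# w_n = P_S(n) n / <n> (degree distribution reached by following an edge):
#   B = <beta^-1>_edge, K = sum_n w_n (n/(n+1)) / beta_n,
#   W = sum_m P_A(m) (m/<m>) * gamma m / (gamma m B + 1).
mf_coefs <- function(dists, params) {
  beta_n <- mf_beta(dists$n, params, dists$mean_n)
  w <- dists$P_S * dists$n / dists$mean_n
  B <- sum(w / beta_n)
  K <- sum(w * (dists$n / (dists$n + 1)) / beta_n)
  W <- sum(dists$P_A * (dists$m / dists$mean_m) *
             params$gamma * dists$m / (params$gamma * dists$m * B + 1))
  list(beta_n = beta_n, w = w, B = B, K = K, W = W)
}

#' Mean-field equilibrium extraction pressures by source degree
#'
#' Solves the degree-binned self-consistency system for the expected Nash
#' extraction pressure on degree-`n` sources,
#' \deqn{\langle q \rangle_n = \frac{1}{\beta_n}\frac{n}{n+1}
#'   \Big[\alpha - \sum_m P_A(m)\frac{m}{\langle m\rangle}
#'   \frac{\gamma m}{\gamma m \langle\beta^{-1}\rangle_e + 1}
#'   \big(\alpha\langle\beta^{-1}\rangle_e - u\big)\Big],}
#' one equation per source degree with positive mass, closed through the
#' edge-weighted mean pressure `u`. The system touches the unknowns only
#' through `u`, so `"reduced"` solves one scalar linear equation and recovers
#' every pressure in closed form; `"full"` assembles and solves the dense
#' linear system. The two agree to machine precision. With `gamma = 0` the
#' solution is the closed form `alpha/beta_n * n/(n+1)`.
#'
#' @param dists a [degree_distributions()].
#' @param params a [game_params()].
#' @param method `"reduced"` (default) or `"full"`.
#' @return numeric vector of pressures named by source degree.
#' @export
mf_equilibrium_pressures <- function(dists, params, method = c("reduced", "full")) {
  method <- match.arg(method)
  co <- mf_coefs(dists, params)
  alpha <- params$alpha
  e_n <- (dists$n / (dists$n + 1)) / co$beta_n
  if (method == "reduced") {
    denom <- 1 - co$K * co$W
    if (abs(denom) < 1e-14) stop("mean-field system is singular for these parameters")
    u <- co$K * alpha * (1 - co$W * co$B) / denom
    qn <- e_n * (alpha - co$W * (alpha * co$B - u))
  } else {
    A <- diag(length(dists$n)) - co$W * (e_n %o% co$w)
    rhs <- e_n * alpha * (1 - co$W * co$B)
    qn <- tryCatch(solve(A, rhs),
                   error = function(e) stop("mean-field system is singular: ",
                                            conditionMessage(e)))
  }
  names(qn) <- dists$n
  qn
}

#' Mean-field equilibrium agent totals by agent degree
#'
#' `<qtot>_m = m / (m gamma <beta^-1>_e + 1) * (alpha <beta^-1>_e - u)` with
#' `u` the edge-weighted mean source pressure.
#'
#' @inheritParams mf_equilibrium_pressures
#' @param qn pressures from [mf_equilibrium_pressures()].
#' @return numeric vector named by agent degree.
#' @export
mf_agent_totals <- function(dists, params, qn) {
  co <- mf_coefs(dists, params)
  u <- sum(co$w * qn)
  qm <- dists$m / (dists$m * params$gamma * co$B + 1) * (params$alpha * co$B - u)
  names(qm) <- dists$m
  qm
}

#' Mean-field per-edge extraction by (agent degree, source degree)
#'
#' `<q>_{m,n} = alpha/beta_n - <q>_n - gamma/beta_n <qtot>_m`. The mean-field
#' closure can predict negative per-edge extraction for extreme degree
#' pairs; such entries are kept and flagged via the `"negative"` attribute,
#' marking where the uncorrelated approximation degrades.
#'
#' @inheritParams mf_agent_totals
#' @param qm agent totals from [mf_agent_totals()].
#' @return matrix with one row per agent degree, one column per source degree.
#' @export
mf_edge_extractions <- function(dists, params, qn, qm) {
  co <- mf_coefs(dists, params)
  qmn <- outer(seq_along(dists$m), seq_along(dists$n), function(i, j) {
    params$alpha / co$beta_n[j] - qn[j] - params$gamma / co$beta_n[j] * qm[i]
  })
  dimnames(qmn) <- list(dists$m, dists$n)
  attr(qmn, "negative") <- any(qmn < 0)
  qmn
}

# b_f of Eq-state pressures under mean field: reallocation conserves the
# total, so b_f = alpha - <q>/<beta^-1> with plain source-weighted means.
mf_bf <- function(dists, params, qn) {
  beta_n <- mf_beta(dists$n, params, dists$mean_n)
  params$alpha - sum(dists$P_S * qn) / sum(dists$P_S / beta_n)
}

#' Mean-field payoff shifts from equilibrium to steady state
#'
#' Expected change in a degree-`m` agent's payoff when myopic reallocation
#' carries the Nash state to the uniform-quality steady state. Two
#' evaluations are returned side by side: `derived`, the first-principles
#' recomputation `<qtot>_m b_f - m * E_edge[<q>_{m,n} b_n]` (quadratic costs
#' cancel because totals are conserved), and `printed`, the closed form
#' `m[(1/<n>)(<n b_n/beta_n> b_f - <n b_n^2/beta_n>)
#'   - gamma <qtot>_m (1/<n>)(<n/beta_n> - <n b_n^2/beta_n>)]`
#' as published. The second bracket of the published form is dimensionally
#' inconsistent with the first-principles result (which carries
#' `<n/beta_n> b_f - <n b_n/beta_n>` there); both are reported rather than
#' silently reconciled, and they coincide at `gamma = 0`. Downstream
#' summaries use `derived`.
#'
#' @inheritParams mf_edge_extractions
#' @return list with numeric vectors `derived` and `printed` (named by agent
#'   degree) and their maximum absolute `discrepancy`.
#' @export
mf_payoff_shifts <- function(dists, params, qn, qm) {
  co <- mf_coefs(dists, params)
  alpha <- params$alpha; gam <- params$gamma
  bn <- alpha - co$beta_n * qn
  bf <- mf_bf(dists, params, qn)
  # plain source-means <x> = sum_n P_S(n) x_n; the 1/<n> prefactor then makes
  # <n x / beta> / <n> an edge-weighted mean
  mS <- function(x) sum(dists$P_S * x)
  qmn <- mf_edge_extractions(dists, params, qn, qm)
  eq_edge_benefit <- as.numeric(qmn %*% (co$w * bn))
  derived <- qm * bf - dists$m * eq_edge_benefit
  printed <- dists$m * ((1 / dists$mean_n) * (mS(dists$n * bn / co$beta_n) * bf -
                                                mS(dists$n * bn^2 / co$beta_n)) -
                          gam * qm * (1 / dists$mean_n) *
                            (mS(dists$n / co$beta_n) - mS(dists$n * bn^2 / co$beta_n)))
  names(derived) <- names(printed) <- dists$m
  list(derived = derived, printed = printed,
       discrepancy = max(abs(derived - printed)))
}

#' Full heterogeneous mean-field solution
#'
#' Computes, from degree distributions alone: equilibrium pressures by source
#' degree, agent totals by agent degree, per-edge extractions, qualities
#' `b_n`, the steady-state quality `b_f`, payoff shifts, and the collective
#' wealth and Gini summaries at equilibrium (`Eq`), reallocation steady state
#' (`SS`) and the efficient benchmark (`Ef`). The efficient benchmark imposes
#' uniform source quality and uniform per-agent totals; under those
#' constraints the welfare program reduces to one scalar quadratic whose
#' maximizer is used in closed form. Gini indices are over the degree-class
#' payoff distribution `{<f>_m, mass P_A(m)}` (within-class variance is
#' invisible to the mean field by construction).
#'
#' @inheritParams mf_equilibrium_pressures
#' @return object of class `meanfield_solution` with fields `qn`, `qm`,
#'   `qmn`, `bn`, `b_f`, `delta_f`, `delta_f_printed`, `f_eq_m`, `f_ss_m`,
#'   `F_Eq`, `F_SS`, `F_Ef`, `G_Eq`, `G_SS`, `negative_qmn`, `params`.
#' @export
mean_field_solution <- function(dists, params) {
  co <- mf_coefs(dists, params)
  qn <- mf_equilibrium_pressures(dists, params)
  qm <- mf_agent_totals(dists, params, qn)
  qmn <- mf_edge_extractions(dists, params, qn, qm)
  bn <- params$alpha - co$beta_n * qn
  bf <- mf_bf(dists, params, qn)
  shifts <- mf_payoff_shifts(dists, params, qn, qm)
  eq_edge_benefit <- as.numeric(qmn %*% (co$w * bn))
  f_eq_m <- dists$m * eq_edge_benefit - params$gamma / 2 * qm^2
  f_ss_m <- f_eq_m + shifts$derived
  names(f_eq_m) <- names(f_ss_m) <- dists$m
  F_Eq <- dists$M * sum(dists$P_A * f_eq_m)
  F_SS <- dists$M * sum(dists$P_A * f_ss_m)
  # efficient benchmark: uniform quality b* = alpha - x for all sources and
  # uniform agent totals; maximize c x (alpha - x) - gamma/(2M) (c x)^2 with
  # c = N <beta^-1> over x >= 0
  binv <- sum(dists$P_S / co$beta_n)
  cc <- dists$N * binv
  x <- params$alpha / (2 + params$gamma * cc / dists$M)
  F_Ef <- cc * x * (params$alpha - x) - params$gamma / (2 * dists$M) * (cc * x)^2
  G_Eq <- gini_weighted(f_eq_m, dists$P_A)
  G_SS <- gini_weighted(f_ss_m, dists$P_A)
  structure(list(qn = qn, qm = qm, qmn = qmn, bn = bn, b_f = bf,
                 delta_f = shifts$derived, delta_f_printed = shifts$printed,
                 f_eq_m = f_eq_m, f_ss_m = f_ss_m,
                 F_Eq = F_Eq, F_SS = F_SS, F_Ef = F_Ef,
                 G_Eq = G_Eq, G_SS = G_SS,
                 negative_qmn = attr(qmn, "negative"),
                 dists = dists, params = params),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("meanfield_solution (gamma = %g, %s capacity)\n",
              x$params$gamma, x$params$scenario))
  cat(sprintf("  F_Eq/F_Ef = %.4f, (F_SS-F_Eq)/F_Ef = %.4f\n",
              x$F_Eq / x$F_Ef, (x$F_SS - x$F_Eq) / x$F_Ef))
  cat(sprintf("  G_Eq = %.4f, G_Eq - G_SS = %.4f, b_f = %.4f\n",
              x$G_Eq, x$G_Eq - x$G_SS, x$b_f))
  invisible(x)
}

#' Sweep the cost parameter gamma
#'
#' One mean-field solution per `gamma`, summarized as the efficiency ratio
#' `F_Eq/F_Ef`, the reallocation gain `(F_SS - F_Eq)/F_Ef`, `G_Eq`, and the
#' Gini reduction `G_Eq - G_SS`.
#'
#' @inheritParams mf_equilibrium_pressures
#' @param gammas nonnegative numeric grid.
#' @return data frame with one row per gamma.
#' @export
gamma_sweep <- function(dists, params, gammas = seq(0, 1, by = 0.05)) {
  if (!length(gammas) || any(gammas < 0)) stop("`gammas` must be a nonnegative grid")
  rows <- lapply(gammas, function(g) {
    p <- game_params(alpha = params$alpha, gamma = g, scenario = params$scenario,
                     beta = params$beta, beta0 = params$beta0)
    sol <- mean_field_solution(dists, p)
    data.frame(gamma = g,
               F_Eq = sol$F_Eq, F_SS = sol$F_SS, F_Ef = sol$F_Ef,
               eff_ratio = sol$F_Eq / sol$F_Ef,
               realloc_gain = (sol$F_SS - sol$F_Eq) / sol$F_Ef,
               G_Eq = sol$G_Eq, G_SS = sol$G_SS,
               gini_reduction = sol$G_Eq - sol$G_SS)
  })
  do.call(rbind, rows)
}
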