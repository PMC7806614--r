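#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Edge arrays are 0-based; `ae[e]` is the agent and `se[e]` the source of edge e.
// For the steady-state solver and the integrator, edges must arrive sorted by
// agent, with CSR offsets `astart` of length M+1 (astart[a] .. astart[a+1]-1).

// Complementarity residual for the Nash contract: for every edge,
// q >= 0, g = alpha - beta q> - beta q - gamma q< <= 0, q*g = 0.
static double nash_residual_impl(const IntegerVector& ae, const IntegerVector& se,
                                 const NumericVector& beta, double alpha, double gamma,
                                 const NumericVector& q,
                                 const std::vector<double>& row,
                                 const std::vector<double>& col) {
  double res = 0.0;
  for (int e = 0; e < ae.size(); ++e) {
    double g = alpha - beta[se[e]] * (col[se[e]] + q[e]) - gamma * row[ae[e]];
    double r = std::fabs(std::min((double)q[e], -g));
    if (r > res) res = r;
  }
  return res;
}

// Cyclic projected coordinate best response on the exact potential
// P = sum_s(alpha q> - beta q>^2/2 - beta sum_a q^2/2) - gamma/2 sum_a q<^2.
// Strict concavity of P makes the fixed point the unique Nash state.
// [[Rcpp::export]]
List cpp_nash_solve(IntegerVector ae, IntegerVector se, NumericVector beta,
                    double alpha, double gamma, int M, int N,
                    NumericVector q0, double tol, int maxit) {
  int E = ae.size();
  NumericVector q = clone(q0);
  std::vector<double> row(M, 0.0), col(N, 0.0);
  for (int e = 0; e < E; ++e) { row[ae[e]] += q[e]; col[se[e]] += q[e]; }
  double res = R_PosInf;
  int it = 0;
  while (it < maxit) {
    ++it;
    for (int e = 0; e < E; ++e) {
      int a = ae[e], s = se[e];
      double qs = col[s] - q[e], qa = row[a] - q[e];
      double qn = (alpha - beta[s] * qs - gamma * qa) / (2.0 * beta[s] + gamma);
      if (qn < 0.0) qn = 0.0;
      col[s] += qn - q[e];
      row[a] += qn - q[e];
      q[e] = qn;
    }
    res = nash_residual_impl(ae, se, beta, alpha, gamma, q, row, col);
    if (res <= tol) break;
  }
  return List::create(_["q"] = q, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = (res <= tol));
}

// [[Rcpp::export]]
double cpp_nash_residual(IntegerVector ae, IntegerVector se, NumericVector beta,
                         double alpha, double gamma, int M, int N, NumericVector q) {
  std::vector<double> row(M, 0.0), col(N, 0.0);
  for (int e = 0; e < ae.size(); ++e) { row[ae[e]] += q[e]; col[se[e]] += q[e]; }
  return nash_residual_impl(ae, se, beta, alpha, gamma, q, row, col);
}

// Projected coordinate ascent on collective wealth
// F = sum_s(alpha q> - beta q>^2) - gamma/2 sum_a q<^2 (concave quadratic).
// [[Rcpp::export]]
List cpp_pareto_solve(IntegerVector ae, IntegerVector se, NumericVector beta,
                      double alpha, double gamma, int M, int N,
                      NumericVector q0, double tol, int maxit) {
  int E = ae.size();
  NumericVector q = clone(q0);
  std::vector<double> row(M, 0.0), col(N, 0.0);
  for (int e = 0; e < E; ++e) { row[ae[e]] += q[e]; col[se[e]] += q[e]; }
  double res = R_PosInf;
  int it = 0;
  while (it < maxit) {
    ++it;
    for (int e = 0; e < E; ++e) {
      int a = ae[e], s = se[e];
      double qs = col[s] - q[e], qa = row[a] - q[e];
      double qn = (alpha - 2.0 * beta[s] * qs - gamma * qa) / (2.0 * beta[s] + gamma);
      if (qn < 0.0) qn = 0.0;
      col[s] += qn - q[e];
      row[a] += qn - q[e];
      q[e] = qn;
    }
    res = 0.0;
    for (int e = 0; e < E; ++e) {
      double g = alpha - 2.0 * beta[se[e]] * col[se[e]] - gamma * row[ae[e]];
      double r = std::fabs(std::min((double)q[e], -g));
      if (r > res) res = r;
    }
    if (res <= tol) break;
  }
  return List::create(_["q"] = q, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = (res <= tol));
}

// Exact water-filling of one agent's conserved total T across its sources,
// holding all other agents fixed: q_e = max(0, (c_e - mu)/beta_e) with
// c_e = alpha - beta_e * (pressure excluding this agent), mu chosen so the
// allocations sum to T. Qualities of the agent's used sources all equal mu.
static void waterfill(int st, int en, const IntegerVector& se,
                      const NumericVector& beta, double alpha, double T,
                      NumericVector& q, std::vector<double>& col) {
  int d = en - st;
  std::vector<double> c(d), binv(d);
  std::vector<int> ord(d);
  for (int i = 0; i < d; ++i) {
    int e = st + i, s = se[e];
    c[i] = alpha - beta[s] * (col[s] - q[e]);
    binv[i] = 1.0 / beta[s];
    ord[i] = i;
  }
  std::sort(ord.begin(), ord.end(), [&](int i, int j) { return c[i] > c[j]; });
  double sa = 0.0, sb = 0.0, mu = 0.0;
  int kuse = d;
  for (int k = 0; k < d; ++k) {
    int i = ord[k];
    sa += c[i] * binv[i];
    sb += binv[i];
    mu = (sa - T) / sb;
    if (k + 1 == d || mu >= c[ord[k + 1]]) { kuse = k + 1; break; }
  }
  double tot = 0.0;
  int imax = -1;
  double qmax = -1.0;
  for (int k = 0; k < d; ++k) {
    int i = ord[k], e = st + i, s = se[e];
    double qn = (k < kuse) ? (c[i] - mu) * binv[i] : 0.0;
    if (qn < 0.0) qn = 0.0;
    col[s] += qn - q[e];
    q[e] = qn;
    tot += qn;
    if (qn > qmax) { qmax = qn; imax = e; }
  }
  // push the float residual of the sum onto the largest allocation so the
  // agent's conserved total is preserved exactly
  if (imax >= 0) {
    double fix = T - tot;
    if (q[imax] + fix >= 0.0) {
      col[se[imax]] += fix;
      q[imax] += fix;
    }
  }
}

// Steady-state residual: for each agent, used sources must attain the maximum
// quality among all its affiliated sources (complementarity contract).
static double steady_residual_impl(const IntegerVector& se, const IntegerVector& astart,
                                   const NumericVector& beta, double alpha,
                                   const NumericVector& q, const std::vector<double>& col,
                                   double qeps) {
  int M = astart.size() - 1;
  double res = 0.0;
  for (int a = 0; a < M; ++a) {
    double bmax = -R_PosInf;
    for (int e = astart[a]; e < astart[a + 1]; ++e) {
      double b = alpha - beta[se[e]] * col[se[e]];
      if (b > bmax) bmax = b;
    }
    for (int e = astart[a]; e < astart[a + 1]; ++e) {
      if (q[e] > qeps) {
        double gap = bmax - (alpha - beta[se[e]] * col[se[e]]);
        if (gap > res) res = gap;
      }
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_steady_solve(IntegerVector ae, IntegerVector se, IntegerVector astart,
                      NumericVector beta, double alpha, int M, int N,
                      NumericVector q0, double tol, int maxit) {
  int E = ae.size();
  NumericVector q = clone(q0);
  std::vector<double> col(N, 0.0), T(M, 0.0);
  for (int e = 0; e < E; ++e) { col[se[e]] += q[e]; T[ae[e]] += q[e]; }
  double res = R_PosInf;
  int it = 0;
  while (it < maxit) {
    ++it;
    for (int a = 0; a < M; ++a)
      if (astart[a + 1] > astart[a]) waterfill(astart[a], astart[a + 1], se, beta, alpha, T[a], q, col);
    res = steady_residual_impl(se, astart, beta, alpha, q, col, 1e-12);
    if (res <= tol) break;
  }
  return List::create(_["q"] = q, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = (res <= tol));
}

// [[Rcpp::export]]
double cpp_steady_residual(IntegerVector ae, IntegerVector se, IntegerVector astart,
                           NumericVector beta, double alpha, int N, NumericVector q) {
  std::vector<double> col(N, 0.0);
  for (int e = 0; e < ae.size(); ++e) col[se[e]] += q[e];
  return steady_residual_impl(se, astart, beta, alpha, q, col, 1e-12);
}

// Projected explicit Euler for the myopic reallocation flow. The interior
// field dq(a,s)/dt = k sum_{s' in S_a} [b(s) - b(s')] is a sum of pairwise
// transfers at rate k[b(s) - b(s')] from the worse source s' to the better
// source s; the boundary projection suppresses exactly those transfers whose
// donor edge is empty (q(a,s') = 0). This reduces to the printed flow in the
// interior, conserves each agent's total by pairing, and its fixed points
// are exactly the complementarity steady states (every used source at the
// agent's top quality). Each Euler step takes the full dt: edges driven
// below zero are clamped to the boundary and the clamped mass is taken back
// proportionally from the agent's inflows, then the agent's total is pinned
// to its stored initial value (float-exact conservation). A fixed step size
// avoids the arbitrarily small time steps that exact zero-crossing
// truncation would force when edges chatter at the boundary.
// [[Rcpp::export]]
List cpp_integrate(IntegerVector ae, IntegerVector se, IntegerVector astart,
                   NumericVector beta, double alpha, double gamma, double k,
                   NumericVector q0, double dt, double t_max, double tol,
                   int record_every, int max_steps) {
  int E = ae.size(), M = astart.size() - 1;
  int N = beta.size();
  const double qeps = 1e-12;
  NumericVector q = clone(q0);
  std::vector<double> col(N, 0.0), b(N, 0.0), d(E, 0.0), row(M, 0.0);
  for (int e = 0; e < E; ++e) { col[se[e]] += q[e]; row[ae[e]] += q[e]; }
  std::vector<double> T0(row);  // conserved per-agent totals
  double cost = 0.0;  // quadratic costs are invariant under reallocation
  for (int a = 0; a < M; ++a) cost += 0.5 * gamma * row[a] * row[a];

  std::vector<double> times, spreads, F0s, Ftots;
  double t = 0.0, t_conv = NA_REAL;
  bool converged = false;
  int step = 0;

  auto observe = [&](double& spread_out, double& F0_out) {
    for (int s = 0; s < N; ++s) b[s] = alpha - beta[s] * col[s];
    double spread = 0.0;
    for (int a = 0; a < M; ++a) {
      double bmax = -R_PosInf, bminused = R_PosInf;
      for (int e = astart[a]; e < astart[a + 1]; ++e) {
        double bs = b[se[e]];
        if (bs > bmax) bmax = bs;
        if (q[e] > qeps && bs < bminused) bminused = bs;
      }
      if (bminused < R_PosInf && bmax - bminused > spread) spread = bmax - bminused;
    }
    double F0 = 0.0;
    for (int s = 0; s < N; ++s) F0 += col[s] * b[s];
    spread_out = spread;
    F0_out = F0;
  };

  double spread, F0;
  observe(spread, F0);
  times.push_back(t); spreads.push_back(spread);
  F0s.push_back(F0); Ftots.push_back(F0 - cost);
  if (spread < tol) { converged = true; t_conv = 0.0; }

  while (!converged && t < t_max && step < max_steps) {
    ++step;
    for (int s = 0; s < N; ++s) b[s] = alpha - beta[s] * col[s];
    // pairwise-projected derivative per agent
    for (int a = 0; a < M; ++a) {
      int st = astart[a], en = astart[a + 1];
      for (int e = st; e < en; ++e) d[e] = 0.0;
      for (int i = st; i < en; ++i) {
        double bi = b[se[i]];
        for (int j = st; j < en; ++j) {
          double bj = b[se[j]];
          if (bi > bj && q[j] > qeps) {  // active transfer j -> i
            double r = k * (bi - bj);
            d[i] += r;
            d[j] -= r;
          }
        }
      }
    }
    // full Euler step with boundary clamping and per-agent rebalancing
    double h = std::min(dt, t_max - t);
    for (int a = 0; a < M; ++a) {
      int st = astart[a], en = astart[a + 1];
      double deficit = 0.0, inflow = 0.0;
      for (int e = st; e < en; ++e) {
        double qn = q[e] + h * d[e];
        if (d[e] > 0.0) inflow += h * d[e];
        if (qn < 0.0) { deficit += -qn; qn = 0.0; }
        d[e] = qn;  // reuse d as the provisional new state
      }
      if (deficit > 0.0 && inflow > 0.0) {
        double fac = deficit / inflow;
        if (fac > 1.0) fac = 1.0;
        for (int e = st; e < en; ++e)
          if (d[e] > q[e]) d[e] -= fac * (d[e] - q[e]);
      }
      // pin the agent's total to its conserved value
      double tot = 0.0, qmax = -1.0; int imax = -1;
      for (int e = st; e < en; ++e) {
        tot += d[e];
        if (d[e] > qmax) { qmax = d[e]; imax = e; }
      }
      double err = tot - T0[a];
      if (imax >= 0 && d[imax] - err >= 0.0) d[imax] -= err;
      for (int e = st; e < en; ++e) {
        col[se[e]] += d[e] - q[e];
        q[e] = d[e];
      }
    }
    t += h;
    if (step % record_every == 0 || t >= t_max) {
      observe(spread, F0);
      times.push_back(t); spreads.push_back(spread);
      F0s.push_back(F0); Ftots.push_back(F0 - cost);
      if (spread < tol) { converged = true; t_conv = t; }
    }
  }
  return List::create(_["q"] = q, _["times"] = wrap(times),
                      _["quality_spread"] = wrap(spreads),
                      _["wealth_costfree"] = wrap(F0s),
                      _["wealth_total"] = wrap(Ftots),
                      _["converged"] = converged, _["convergence_time"] = t_conv,
                      _["steps"] = step, _["t_end"] = t);
}
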