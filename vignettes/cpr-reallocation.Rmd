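---
title: "Extraction games on bipartite agent-resource networks: model, solvers, and mean-field theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extraction games on bipartite agent-resource networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprgame)
```

## The model

A population of $M$ agents extracts benefits from $N$ common-pool resource
(CPR) sources through a static bipartite affiliation network: an edge
$(a, s)$ means agent $a$ has access to source $s$. Agent $a$ exerts a
nonnegative extraction effort $q(a,s)$ on each affiliated source; we write
$\overleftarrow{q}(a) = \sum_s q(a,s)$ for the agent's total effort and
$\overrightarrow{q}(s) = \sum_a q(a,s)$ for the *extraction pressure* on a
source. Sources are rivalrous: the benefit per unit effort (the *quality*)
declines linearly with pressure,
$$b(s) = \alpha - \beta(s)\,\overrightarrow{q}(s),$$
and an agent's payoff is
$$f(a) = \sum_{s} q(a,s)\,b(s) - \frac{\gamma}{2}\,\overleftarrow{q}(a)^2 ,$$
where $\gamma \ge 0$ encodes diminishing marginal utility of effort.
Quality is deliberately *not* floored at zero: over-exploitation is
representable, and the equilibrium solvers need the unclipped linear form.

Two capacity scenarios resolve the per-source slope $\beta(s)$:

* **uniform** — $\beta(s) \equiv \beta$: all sources degrade alike per unit
  of total pressure;
* **degree-proportional** — $\beta(s) = \beta_0 \langle n\rangle / n(s)$:
  sources degrade per unit of pressure *per user*, so high-degree sources
  are proportionally more robust.

Three extraction states organize everything the package computes:

* the **Nash equilibrium**, the unique state in which no agent can gain by
  unilaterally changing its own efforts;
* the **reallocation steady state**, reached when agents myopically shift
  effort from lower- to higher-quality affiliated sources while conserving
  their totals;
* the **Pareto efficient state**, which maximizes collective wealth
  $F = \sum_a f(a)$.

The scientific questions are how the network's degree distributions shape
the inefficiency of equilibrium (a price of anarchy, $F_{Eq}/F_{Ef}$), how
much of that inefficiency myopic reallocation alone recovers
($(F_{SS}-F_{Eq})/F_{Ef}$), and how the recovered wealth is distributed
across agent degree classes (Gini index shifts $G_{Eq}-G_{SS}$).

## Solvers

The game admits an exact potential
$$P = \sum_s\Big(\alpha \overrightarrow{q}(s)
      - \tfrac{\beta(s)}{2}\overrightarrow{q}(s)^2
      - \tfrac{\beta(s)}{2}\sum_a q(a,s)^2\Big)
      - \frac{\gamma}{2}\sum_a \overleftarrow{q}(a)^2,$$
whose gradient with respect to $q(a,s)$ is exactly the agent's marginal
payoff on that edge. $P$ is strictly concave, so its maximizer over the
nonnegative orthant is the unique Nash state. `nash_equilibrium()` maximizes
$P$ by projected cyclic coordinate best response (each edge update is the
exact scalar maximizer), which for a strictly concave quadratic is
guaranteed to converge; the returned state is certified *post hoc* against
the complementarity contract
$q \ge 0,\; \partial f/\partial q \le 0,\; q\cdot\partial f/\partial q = 0$
on every edge (`nash_residual()`, default tolerance $10^{-9}$).

`pareto_efficient()` maximizes $F$ the same way. At $\gamma = 0$ the
welfare decouples source by source (each source's optimal pressure is
$\alpha/2\beta(s)$) and the agent-level split is indeterminate; the solver
returns the minimum-Euclidean-norm maximizer — an equal split among each
source's users — in closed form, deterministically. For $\gamma > 0$ the
optimal value is unique, though the edge-level allocation can remain
degenerate along bipartite cycles; the solver is deterministic (zero start,
fixed sweep order), and all reported summaries depend only on the unique
pressures, loads, and optimal value.

`steady_state()` computes reallocation fixed points: states with the same
per-agent totals as the input in which no agent still faces a quality
gradient, i.e. for every agent all *used* sources attain the maximum
quality among its affiliated sources. These are the solutions of a linear
complementarity problem, and equivalently the maximizers of the aggregate
surplus $\Phi = \sum_s (\alpha\overrightarrow{q} -
\beta(s)\overrightarrow{q}^2/2)$ subject to fixed agent totals. The solver
is block-coordinate ascent on $\Phi$: one exact *water-filling* step per
agent (allocate the conserved total so all its used sources share one
quality $\mu(a)$), swept cyclically. Blockwise-exact ascent of a concave
objective over a product of simplices converges; ties among equally good
sources are resolved by the deterministic edge order (sorted source ids).
The pressures $\overrightarrow{q}(s)$ of the steady state are unique
($\Phi$ is strictly concave in them) even where the edge allocation is not,
which is why cross-checks against the dynamics compare pressures.

## Reallocation dynamics

The myopic update rule is the quality-chasing flow
$$\frac{d}{dt} q(a,s) = k \sum_{s' \in S_a}\big[b(s) - b(s')\big],$$
a sum of pairwise transfers at rate $k\,[b(s)-b(s')]$ from each
worse source $s'$ to each better source $s$ of the same agent. The rate
constant $k$ is a pure time scale (default 1); every fixed-point result is
$k$-invariant, and convergence-time comparisons hold $k$ and the step size
fixed across ensembles.

As printed, the flow can drive efforts negative. `integrate_reallocation()`
therefore integrates a *projected* flow: a pairwise transfer is suppressed
exactly when its donor edge is empty ($q(a,s') = 0$). This projection (i)
coincides with the raw flow everywhere in the interior, (ii) conserves each
agent's total identically because transfers are paired, and (iii) has as
its fixed points exactly the complementarity steady states above. We note
for completeness that a coarser projection — zeroing the negative part of
the aggregated derivative and rescaling the inflows — is *not* equivalent:
it admits stall states in which an agent's positive-effort source should
donate to a better unused source but all of the agent's below-average
sources sit at zero, freezing the aggregate rule short of the steady state.
The pairwise form has no such states.

Integration is explicit Euler at a fixed step: an edge driven below zero
within a step is clamped to the boundary and the clamped mass is taken back
proportionally from that agent's inflows, after which the agent's total is
pinned float-exactly to its initial value — so conservation holds exactly
over arbitrarily long horizons. We deliberately do *not* truncate the step
to the first zero crossing: edges can chatter at the boundary while the
active sets sort themselves out, and exact-crossing truncation then forces
arbitrarily small time steps (the integration effectively stalls), whereas
the clamped full step commits an $O(dt^2)$ local error only at the
boundary. The default step $dt = 0.01 / (k \max\beta \max_a m(a))$ is well
inside the stability region (the fastest local relaxation rate of an
agent's internal quality-equalization mode is about $k\,\beta\,m(a)$). Convergence is
declared when the *quality spread* — the largest gap, over agents, between
the best affiliated quality and the worst quality among sources the agent
still uses — falls below `tol` (default $10^{-8}$); this spread is the
complementarity residual of the steady-state contract, so "converged" means
"is a steady state to within `tol`".

Along any trajectory the cost-free collective wealth
$F_0 = \sum_s \overrightarrow{q}(s) b(s)$ is non-decreasing: its time
derivative equals $k \sum_a \sum_{s,s'} [b(s)-b(s')]^2 / 2$ in the
interior, and the projected flow only removes negative contributions. This
is the trajectory-wise face of the equalization theorem: for *any* initial
state, the steady-state wealth $F_f = \sum_c Q_c b_f(c)$ (components $c$,
conserved component pressure $Q_c$, common final quality
$b_f = \alpha - \sum_s \overrightarrow{q}(s) / \sum_s \beta(s)^{-1}$)
satisfies $F_f \ge F_0$ by the Cauchy–Schwarz inequality applied to
$X = \sqrt{\beta(s)}\,\overrightarrow{q}(s)$, $Y = 1/\sqrt{\beta(s)}$, with
equality exactly when $\beta(s)\overrightarrow{q}(s)$ is constant within
each component. Quadratic costs are invariant under reallocation, so the
cost-free convention loses nothing in these comparisons. The final quality
is computed per connected component because the flow cannot transport
effort between components.

## Synthetic networks: what the generator emulates

`generate_ensemble()` emulates ensembles of bipartite networks indexed by a
source-degree kind — delta (**D**), normal (**N**), power law (**PL**) —
and an agent-degree kind — uniform (**U**), random (**R**),
scale-free-type (**SF**) — at the study conditions $M = N = 50$ and mean
degrees $\langle m\rangle = \langle n\rangle = 5$. The degree samplers are:
constant `round(mean)` for D/U; rounded Normal(mean, $\sigma = 1.5$)
truncated at 1 for N; a multinomial stub-throw (binomial-like margins, empty
bins raised to degree 1) for R; and a discrete power law
$p(d) \propto d^{-\tau}$ on $1..(size-1)$ for PL/SF, with $\tau$ solved
numerically so the truncated mean hits the target (about 2.45 for mean 5 on
$1..49$). $\sigma$ and the power-law construction are surrogates chosen
once; they reproduce the qualitative heterogeneity ordering D < N < PL
(source side) and U < R < SF (agent side) that drives every result, but no
claim is made that they match any particular empirical network family.

Sampled degree pairs must be realizable as a *simple* bipartite graph.
Totals are first reconciled by unit increments/decrements at uniformly
random nodes — raising the deficient side or lowering the excess side with
equal probability, so the expected total is preserved. Joint heavy tails
(PL sources with SF agents) are then Gale–Ryser-infeasible for roughly half
of raw draws at $M = N = 50$; rejection sampling would censor exactly the
hub-rich draws and bias the pooled mean degree down by more than 10%, so
infeasible pairs are instead *repaired minimally*: decrement the largest
hub, increment a random lower-degree node on the same side, repeat until
feasible. Totals and means are untouched; only the extreme joint tail is
trimmed. A degree exceeding the opposite-side size is rejected outright.
The realization itself is a maximal-first greedy construction (always
succeeds for feasible pairs) randomized by $20E$ attempted double-edge
swaps, which hold all degrees fixed and never create duplicates. We chose
this over configuration-model stub pairing because pairing plus duplicate
repair fails outright on hub-on-hub draws, and any resampling there
reintroduces the censoring bias. No degree–degree correlation is imposed
beyond what simple-graph feasibility itself forces — an important caveat
for the mean-field comparison below.

What passing tests on these synthetic ensembles do *not* show: real CPR
affiliation networks have assortativity, clustering, and degree
distributions outside this three-by-three family; results here quantify the
effect of marginal degree heterogeneity alone.

## Heterogeneous mean-field theory

Binning nodes by degree and assuming no degree–degree correlations closes
the equilibrium conditions on one unknown per source degree,
$\langle\overrightarrow{q}\rangle_n$. The package solves the linear system
both directly (dense solve over the degrees with positive mass) and through
its scalar reduction — the system couples to the unknowns only through the
edge-weighted mean pressure
$u = \sum_n P_S(n) (n/\langle n\rangle) \langle\overrightarrow{q}\rangle_n$,
so one scalar linear equation determines $u$ and every pressure follows in
closed form. The two routes agree to $10^{-10}$ by construction and are
cross-checked in the tests. At $\gamma = 0$ the solution is
$\langle\overrightarrow{q}\rangle_n = (\alpha/\beta_n)\, n/(n+1)$ — which
is also the *exact* per-network equilibrium pressure for uniform capacity,
since at zero cost a source's equilibrium decouples from the rest of the
network. Expected agent totals $\langle\overleftarrow{q}\rangle_m$,
per-edge extractions $\langle q\rangle_{m,n}$, qualities
$b_n = \alpha - \beta_n \langle\overrightarrow{q}\rangle_n$, and the common
steady-state quality $b_f$ follow in closed form. Degrees with zero mass
are excluded from the system, so no spurious singularities arise.

The expected payoff shift of a degree-$m$ agent under reallocation from
equilibrium is computed two ways and reported side by side: a
first-principles recomputation
$$\Delta\langle f\rangle_m =
  \langle\overleftarrow{q}\rangle_m b_f
  - m \sum_n P_S(n)\frac{n}{\langle n\rangle}\langle q\rangle_{m,n} b_n$$
(quadratic costs cancel because totals are conserved), and the closed form
with the bracket structure
$m[(1/\langle n\rangle)(\langle n b_n/\beta_n\rangle b_f - \langle n
b_n^2/\beta_n\rangle) - \gamma\langle\overleftarrow{q}\rangle_m \cdot
(\ldots)]$, where the second bracket is evaluated as
$\langle n/\beta_n\rangle - \langle n b_n^2/\beta_n\rangle$ in
`delta_f_printed`. That second bracket is dimensionally inconsistent with
the first-principles result, which carries
$\langle n/\beta_n\rangle b_f - \langle n b_n/\beta_n\rangle$ in that
position; we treat it as a typographical slip in the closed form, report
both evaluations without reconciling them (they coincide at $\gamma = 0$,
where the suspect term is multiplied by
$\gamma\langle\overleftarrow{q}\rangle_m = 0$), and use the
first-principles value in all downstream summaries.

Mean-field summaries take expectations over degree classes:
$F_{Eq} = M\sum_m P_A(m)\langle f\rangle_m$, $F_{SS} = F_{Eq} +
M\sum_m P_A(m)\Delta\langle f\rangle_m$, and the efficient benchmark
$F_{Ef}$ imposes the two structural properties of efficient states —
uniform quality across sources and uniform totals across agents — under
which the welfare program collapses to a scalar quadratic with maximizer
$\alpha - b^* = \alpha / (2 + \gamma N\langle\beta^{-1}\rangle/M)$, used in
closed form. Gini indices are taken over the degree-class payoff
distribution $\{\langle f\rangle_m,\ P_A(m)\}$; within-class variance is
invisible to the mean field by construction, so the class-level Gini is the
like-for-like comparison, while simulation Gini indices are over individual
agents. The two are never mixed in one number.

Two structural predictions follow immediately and are encoded as tests: at
$\gamma = 0$ payoff gains are proportional to degree, so the Gini index
does not change under reallocation for *any* degree distributions; and for
delta source distributions the mean field predicts no shifts at all — on
actual D-source networks reallocation still helps, because realized
networks have within-class quality variation the closure cannot see.
Simulated gains therefore systematically meet or exceed the mean-field
prediction (`compare_sim_meanfield()` reports the signed deviations).

## Numerical choices and known limitations

* **Tolerances.** Solver complementarity residuals $10^{-9}$ by default
  (on the $\alpha = \beta = 1$ scale), iteration budget $10^5$ sweeps;
  dynamics spread tolerance $10^{-8}$; all exposed as arguments.
* **Determinism.** All stochastic steps consume child seeds
  $(\text{seed} + 1000003\,i) \bmod 2147483629$ of a master seed, so any
  subset of realizations is reproducible in isolation; solvers are
  deterministic given the canonical (agent, source) edge order.
* **Degenerate inputs.** Agents with a single source never move under
  reallocation; zero-total agents water-fill to zero; disconnected networks
  are handled per component throughout; Gini is refused on nonpositive
  totals and warns on negative payoffs.
* **Problem sizes.** Study conditions are $M = N = 50$, mean degrees 5,
  with 100 realizations per ensemble as the default desk-scale profile of
  the design (the full-scale design uses $10^3$); statistical assertions in
  the tests are calibrated to that profile.
* **Mean-field validity.** The uncorrelated closure degrades where
  $\langle q\rangle_{m,n} < 0$ appears (flagged by `negative_qmn`): with
  50 sources, a degree-45+ hub agent *must* attach to nearly every source,
  so the no-correlation ansatz fails structurally. For the PL-SF ensemble
  at $\gamma = 0.2$ the degree-resolved equilibrium pressures deviate from
  simulation by roughly 25% on average (versus at most about 3.5% for the
  other eight ensembles); predictions for such joint-heavy-tailed ensembles
  at $\gamma > 0$ should be treated as qualitative only.
* **Convergence-time comparisons** across ensembles hold $k$, $dt$, and
  the spread tolerance fixed; times are reported in model time, not steps.
  Because the flow is $\gamma$-free, its intrinsic equalization rate is
  compared from seeded random feasible initial states; there the mean
  convergence time decreases with agent-degree heterogeneity (SF < R < U at
  fixed N sources) at every tolerance we examined. From *Nash* starts the
  comparison is confounded by the initial condition itself — at $\gamma=0$
  equilibrium qualities are already equal within each source-degree class,
  and at $\gamma>0$ hub agents start with many boundary edges whose active
  sets resolve slowly — and the ordering is not recovered there.

## A worked micro-example

```{r micro}
net <- bipartite_network(cbind(c(1, 1, 2), c(1, 2, 2)))
p <- game_params(alpha = 1, beta = 1, gamma = 0.2)

eq <- nash_equilibrium(net, p)
ss <- steady_state(net, p, eq$state)
ef <- pareto_efficient(net, p)

c(F_eq = collective_wealth(eq$state, net, p),
  F_ss = collective_wealth(ss$state, net, p),
  F_ef = collective_wealth(ef$state, net, p))
```

```{r microdyn}
tr <- integrate_reallocation(eq$state, net, p, t_max = 200)
max(abs(source_pressure(tr$final_state, net) - source_pressure(ss$state, net)))
```

## An ensemble in one call

```{r ensemble, eval = FALSE}
spec <- ensemble_spec("PL", "R", n_realizations = 100, seed = 1)
out <- run_ensemble(spec, gammas = c(0, 0.2))
print(out)
compare_sim_meanfield(out)$per_gamma
```
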