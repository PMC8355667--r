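---
title: "Methods: SIS contagion on hypergraphs and its spectral analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIS contagion on hypergraphs and its spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypersis)
```

## The model

A hypergraph $H = (V, E)$ records group interactions: $n$ nodes and $m$
hyperedges, each a non-empty node subset. Duplicate hyperedges are
allowed (two distinct groups may have identical membership; they add
co-membership weight), duplicate nodes within a hyperedge are not. Each
node carries a binary state $X_i(t)$; infected nodes recover at rate
$\delta$, and a susceptible node $i$ is infected at rate
$$\beta \sum_{h \in E} I_{ih}\, f\Big(\sum_j X_j(t) I_{jh}\Big),$$
where $I$ is the $n \times m$ incidence matrix and $f$, with $f(0)=0$,
translates a hyperedge's infectious head-count into risk. The inner
count formally includes node $i$ itself, which is harmless: the rate is
only consumed while $X_i = 0$. In the partitioned variant the hyperedges
are split into $K$ categories with responses $f_1, \dots, f_K$ and the
rates add across categories.

The process is a continuous-time Markov chain whose only absorbing state
is all-susceptible. Two simulators are provided. `simulate_exact()` is
event-driven: waiting times are exponential in the current total rate and
events are chosen proportionally, so trajectories follow the chain's law
exactly. `simulate_discrete()` implements the synchronous one-draw
scheme: per step of length $\Delta t$ a single uniform $r_i$ per node
decides the flip, infection with probability $1 - e^{-\text{rate}_i
\Delta t}$, recovery with probability $1 - e^{-\delta \Delta t}$, both
computed from the pre-step state. Simultaneous flips are permitted; no
sequential-update variant exists. The exact simulator is the reference
for the stochastic theory; the discrete one is the default for figure
reproduction and converges to the exact law as $\Delta t \to 0$ (the
test suite measures the sup-distance of ensemble mean curves at
$\Delta t \in \{0.1, 0.05, 0.025\}$ against the event-driven curves).

The mean-field approximation replaces $X$ by the probabilities
$p_i(t) = P(X_i(t) = 1)$ and exchanges expectation with $f$:
$$\dot p_i = \beta \sum_h I_{ih} f\Big(\sum_j p_j I_{jh}\Big)(1 - p_i)
  - \delta p_i.$$
The self-term $p_i$ stays inside the inner sum, exactly as the ODE is
derived; no correction is applied, because the discrepancy with the exact
process is part of the approximation being studied. For concave $f$ the
exchanged rates over-estimate the true expected rates (Jensen), so the
mean field upper-bounds the expected infected fraction; the suite checks
this ordering empirically against matched-seed ensembles. For threshold
responses no ordering is asserted.

## Spectral quantities and the conventions behind them

Everything spectral is built from the co-membership matrix
$W = I I^\mathsf{T}$, whose off-diagonal entries count shared hyperedges
and whose diagonal holds node degrees.

* **The diagonal of $W$ is kept.** The linearization of the mean field at
  zero is exactly $\beta f'(0) W - \delta I$ *with* the degree diagonal,
  so all thresholds use it. For an ordinary graph $W = A + D$, which
  makes the reported $\beta_c$ conservative relative to the classical
  adjacency condition $\lambda(A)\beta/\delta < 1$; `comembership(H,
  diagonal = FALSE)` exposes the zero-diagonal variant for that
  comparison, and a test asserts $\lambda(W) \ge \lambda(A)$ on random
  graphs.
* **Laplacian convention.** $\Delta = D - W_{\text{off}}$ is the standard
  weighted-graph Laplacian of the *off-diagonal* part of $W$ (self-loops
  do not change cut weights), $D_{ii} = \sum_{j \ne i} W_{ij}$. This
  choice makes the Cheeger inequality $2\eta \ge \lambda_c(\Delta)$
  applicable, which the suite verifies by brute force on small connected
  instances. The number of numerically zero eigenvalues (relative
  tolerance $10^{-8}$ by default) equals the number of connected
  components, cross-checked against graph traversal.
* **Thresholds.** `spectral_threshold()` computes
  $\lambda(\sum_k s_k W^{(k)})$ with $s_k = f_k'(0)$
  (`mode = "derivative_at_zero"`) or the concave-majorant slope
  (`mode = "majorant"`): $f'(0)$ for concave families, $c_2/c_1$ for the
  step, $(e_{\max}-1-c)/(e_{\max}-1)$ for the hinge, and a generic
  $\max_x f(x)/x$ fallback over the attainable integer range for any
  other non-concave family — the fallback is an extension beyond the
  analysed cases and is flagged in the report. Step and hinge have
  $f'(0) = 0$, so their derivative-at-zero condition is vacuously true
  for every $\beta$; the report then labels itself local-only and
  `extinction_bounds()` refuses to emit stochastic bounds until the
  majorant mode is used. Eigenvalues come from dense symmetric solvers
  below $n = 2000$ and power iteration (relative tolerance $10^{-9}$)
  above; $W$ is positive semi-definite, so power iteration converges to
  $\lambda_{\max}$.
* **A caveat on eigenvalue monotonicity.** The auxiliary monotonicity
  statement "subtracting a non-negative diagonal cannot raise the largest
  eigenvalue" is provable by quadratic forms for the *symmetric part* of
  an arbitrary matrix, and for the matrix itself when it is symmetric.
  The max-real-part analogue for general non-symmetric matrices is false
  (random search produces violations), so the property tests assert
  exactly the two true forms — which is also all the global-stability
  argument uses.

## Extinction and non-extinction certificates

For concave $f$ the infected process is stochastically dominated by the
integer-valued severity process with linear rates $\beta f'(0) W$ (up)
and $\delta$ (down); its mean solves a linear ODE, giving
$$P\Big(\sum_i X_i(t) > 0\Big) \le n i_0\, e^{(\beta f'(0) \lambda(W) -
\delta)t}, \qquad
E[\tau] \le \frac{\log n + 1}{\delta - f'(0)\beta\lambda(W)}.$$
`simulate_severity_chain()` implements the dominating process as a test
oracle: its mean is checked against the matrix exponential, and the
domination itself against matched ensembles. The severity process is
unbounded, so simulation carries a configurable cap and reports if it was
hit, keeping the domination test honest.

In the other direction, define the boundary pressure
$E(S, f) = \sum_{i \in S}\sum_h I_{ih} f(|h \cap S^c|)$ and
$\eta(H, m, f) = \min_{1 \le |S| \le m} E(S, f)/|S|$. With $f$ the
identity, $E(S, \mathrm{Id})$ is exactly the weighted cut and $\eta$ the
Cheeger constant of the $W$-graph. When $f$ is concave and non-decreasing
the chord bound $f(e_{\max}-1)/(e_{\max}-1)\, x \le f(x)$ on the
attainable range links the two, and the infected count dominates a
birth–death chain with up-rate coefficient $\beta
\frac{f(e_{\max}-1)}{e_{\max}-1}\eta(H,m)$. `nonextinction_certificate()`
assembles $r = \frac{(e_{\max}-1)\delta}{f(e_{\max}-1)\beta\eta(H,m)}$,
$m = \lfloor n/2 \rfloor$, and for $r < 1$ the horizon
$\lfloor r^{-m+1}\rfloor / (2m)$ with nominal survival probability
$1 - re$. Two honesty rules apply. First, the printed bound carries an
unquantified $O(r^m)$ correction whose constant is unknown; it is
surfaced as a caveat string and never folded into a pass/fail decision
(the rendering of the horizon expression itself is ambiguous in the
source material; $\lfloor r^{-m+1}\rfloor/(2m)$ is the reading
implemented, and the Monte-Carlo check of the horizon is correspondingly
not a hard gate). Second, $\eta$ is Cheeger-like and NP-hard-flavoured:
brute enumeration is exact but refuses beyond a subset budget
(default $5\times 10^5$), and the greedy add/drop/swap search returns an
*upper* bound on $\eta$, hence a *lower* bound on $r$ — the certificate
can then overstate persistence, and the report labels the direction
explicitly rather than pretending precision.

## Numerical choices

* **Euler clamping.** Explicit Euler with large steps can leave
  $[0,1]^n$; steps are projected back and every projected entry is
  counted in `clamp_events` instead of being silently accepted, since the
  ODE's derivation presumes probabilities. The adaptive reference
  integrator (embedded Cash–Karp RK45 with standard step control — no
  ODE-solver package is assumed available) projects only after accepted
  steps and reports the worst pre-projection excursion; at tolerance
  $10^{-8}$ excursions stay below $10^{-6}$ in the forward-invariance
  test.
* **Derivatives.** $f'(0)$ is stored analytically per family — thresholds
  must be exact, so numerical differentiation is never used for them. At
  kink points (cap of `capped_linear`, jump of `step`, knee of `hinge`)
  the Jacobian uses the one-sided derivative from below and flags the
  result as non-differentiable.
* **Decay detection.** `equilibrium_norm_decay()` requires the trailing
  half of the norm sequence to be monotone non-increasing *and* still
  shrinking (final value below 99% of the tail's start, or essentially
  zero); a monotone approach to a non-zero endemic plateau is thereby not
  mistaken for extinction.
* **Norms** are Euclidean throughout.
* **Degenerate inputs.** Empty hyperedge sets give $\lambda = 0$ and
  $\beta_c = \infty$ (every $\beta$ subcritical); $i_0 = 0$ trajectories
  are extinct at $t = 0$; $\beta = 0$ is a pure death process. Size-1
  hyperedges are rejected by the generator but tolerated by the reader
  with a warning (they contribute only diagonal weight).

## Seeds and reproducibility

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state. Ensembles derive per-run seeds as `base_seed + run`,
so runs are reproducible and independent of execution order. By default
ensemble runs share one initial Bernoulli($i_0$) state (the protocol used
for averaged figure curves); `share_init = FALSE` redraws per run, which
is what the i.i.d.-start extinction theory assumes and what the
acceptance test for the survival bound uses. The experiment layer starts
the mean-field ODE from the same realized initial state that the
stochastic ensemble shares, so the two models are compared from matched
conditions; with a constant-$i_0$ start instead, the $t=0$ mismatch
between $i_0$ and the realized infected fraction would masquerade as an
ordering violation.

## The synthetic ensemble: what it does and does not emulate

`random_hypergraph()` draws, for each size $s$ with count $c_s$, $c_s$
independent hyperedges as uniform random $s$-subsets (without
replacement within a hyperedge; duplicates across hyperedges possible).
The generation law behind the reference experiments is not fully
specified beyond the composition, so independent uniform subsets — the
simplest law consistent with it — is adopted once and not revisited. The
default experimental world follows the stated protocols: $n = 400$,
compositions 300 or 400 edges / 200 size-3 / 100 size-4 / 50 size-5,
$\delta = 1$, $\Delta t = 0.05$ (0.1 for the threshold-sweep protocol),
$i_0 = 0.5$, terminal sampling at $t = 150$, ensembles of 10 (time
series) or 5 (threshold sweep) runs sharing hypergraph and initial
state.

This ensemble is homogeneous: every node is exchangeable, degrees
concentrate, and $\beta_c$ varies only a few percent across
realizations. Real contact data have heavy-tailed group memberships,
community structure and degree–size correlations, all of which move
$\lambda(W)$ substantially. A green acceptance run therefore establishes
that the implementation reproduces the stated quantities *on this stated
world* — the headline $\beta_c$ values are reproduced as ensemble means
within the spread expected given that the original fixed hypergraph
realization is unpublished (the arctan-family mean sits $\approx 2$–$3\%$
below the printed value; the log-family mean matches to three decimals) —
not that the model is calibrated to any real epidemic.

## Known limitations

* SIS only: no exposed/removed compartments, vaccination, or
  time-varying $\beta$; hyperedges are static and unweighted.
* The mean field is the naive first-moment closure; no pairwise or
  higher-order closures, and no bifurcation/hysteresis analysis of the
  supercritical regime.
* `eta()`'s greedy search carries no approximation guarantee; reports
  always name the method used.
* The text file dialect identifies nodes by label only, so isolated
  nodes and index order do not survive a text round trip (the JSON
  dialect preserves both).
* Thresholds sharper than $\lambda(W)$-based ones (which use only
  pairwise co-membership information) are out of scope.
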