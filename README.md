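# hypersis

Stochastic SIS epidemics on hypergraphs, with spectral thresholds for
extinction.

## The problem

Classical network SIS models place individuals on a contact *graph*: a
susceptible node `i` becomes infected at rate `β Σ_j A_ij X_j`, linear in
its number of infectious neighbours, and the disease dies out whenever
`λ(A) β / δ < 1`. Real contact happens in *groups* — households, offices,
gyms — and within a group the risk need not be linear in the number of
infectious members. `hypersis` models the population as a hypergraph
`H = (V, E)`: each hyperedge `h` is a group, and a susceptible node `i`
becomes infectious at rate

```
β Σ_{h ∈ E} I_ih f( Σ_j X_j I_jh )
```

where `I` is the node-by-hyperedge incidence matrix, `X ∈ {0,1}^n` the
infection state, and `f` (with `f(0) = 0`) the *infection response* of a
hyperedge to its number of infectious members. Concave `f` (e.g.
`arctan`, `a·log(1+x)`, `min(x, c)`) captures **collective suppression**
— each extra infectious group member adds less risk; threshold responses
(`c₂·1(x ≥ c₁)`, `max(0, x − c)`) capture **collective contagion** —
spread only starts once enough members are infectious. Hyperedges may be
partitioned into `K` categories (by size, venue type, ...), each with its
own response `f_k`. Recovery is at constant rate `δ`.

The central objects are the co-membership matrix `W = I Iᵀ` (so `W_ij`
counts groups shared by `i` and `j`, and `W_ii` is the degree) and the
spectral threshold

```
β λ( Σ_k f_k'(0) W^(k) ) / δ < 1        β_c := δ / λ( Σ_k f_k'(0) W^(k) )
```

Below `β_c` the zero-infection state is asymptotically stable for the
mean-field ODE (locally for any response, globally for concave ones) and
the exact stochastic model dies out exponentially fast, with
`P(any infection at t) ≤ n i₀ e^{(β c_f λ − δ) t}` and
`E[τ] ≤ (log n + 1)/(δ − β c_f λ)`. For non-concave responses the slope
`c_f` of a linear majorant of `f` (e.g. `c₂/c₁` for the step response)
replaces `f'(0)`. A complementary Cheeger-type certificate, built from
the Laplacian gap `λ_c(Δ)` and the isoperimetric constant
`η(H, m) = min_{|S| ≤ m} E(S, Id)/|S|`, rules *out* quick extinction when
infection pressure across every small cut is strong.

## What the package provides

- `hypergraph()`, `random_hypergraph()`, `read_hypergraph()` /
  `write_hypergraph()` (hyperedge-list text and JSON dialects),
  `incidence()`, `comembership()`, `partition_comembership()`,
  `laplacian()`;
- `rate_function()` / `rate_family()` — identity, `min(x,c)`,
  `a·log(1+x)`, `arctan`, step and hinge responses, with exact
  derivatives at zero, concavity certification and majorant slopes;
- exact model simulators: event-driven `simulate_exact()` (the true
  continuous-time Markov chain), the synchronous single-draw
  discrete-time scheme `simulate_discrete()` / `step_discrete()`, and
  `run_ensemble()`; plus the analysis oracles
  `simulate_severity_chain()` (dominating linear-rate process) and
  `simulate_bounding_birth_death()`;
- mean field: `meanfield_rhs()`, `integrate_euler()`,
  `integrate_adaptive()` (embedded RK45 reference), analytic
  `jacobian()`, `equilibrium_norm_decay()`;
- spectral analysis: `effective_matrix()`, `spectral_threshold()`,
  `extinction_bounds()`, `subset_pressure()`, `eta()` (brute/greedy),
  `nonextinction_certificate()`, `symmetric_part()`;
- a config-driven experiment layer (`experiment_config()`,
  `run_figure_protocol()`, `compare_models()`, `write_experiment()`) and
  a CLI (`inst/cli/hypersis.R`) with `generate`, `simulate`, `meanfield`,
  `threshold`, `bounds` and `experiment` subcommands.

## Worked example

A random hypergraph on `n = 400` nodes with 400 pairwise edges, 200
size-3, 100 size-4 and 50 size-5 hyperedges, categorized by size; linear
response on edges, `2·log(1+x)` on larger groups; `δ = 1`:

```r
library(hypersis)
H <- random_hypergraph(400, c(`2` = 400, `3` = 200, `4` = 100, `5` = 50),
                       seed = 42, partition_by_size = TRUE)
fam  <- rate_family("identity", "log1p:a=2", "log1p:a=2", "log1p:a=2")
pars <- sis_params(beta = 0.02, delta = 1, i0 = 0.5)

spectral_threshold(H, fam, pars)
#> Spectral threshold report
#>   decomposition: beta = 0.02 | lambda = 37.8253 | c_f = 1
#>   beta_c = 0.0264374   condition beta * c_f * lambda / delta < 1: TRUE
#>   basis: global (concave) + stochastic-exponential (concavity certified: TRUE)

extinction_bounds(spectral_threshold(H, fam, pars), 400, 0.5, pars)
#> Extinction bounds: growth rate -0.243495, E[tau] <= 28.713

run_ensemble(H, pars, fam, T = 30, n_runs = 10, base_seed = 42, dt = 0.05)
#> SIS ensemble: 10 runs, n = 400, final mean fraction 0, final survival 0
```

Read: the slope-weighted co-membership matrix has `λ = 37.8`, so the
critical infection strength is `β_c ≈ 0.0264`. At `β = 0.02 < β_c` the
survival probability decays like `e^{-0.243 t}`, expected extinction is
bounded by `t ≈ 28.7`, and indeed all 10 stochastic runs (half the
population initially infected) are extinct by `t = 30`. Raising `β`
above `0.0264` flips the picture to a persistent endemic state.

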