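# pbpmcmc — posterior-based proposals for MCMC

Bayesian inference for models with many latent variables routinely stalls on
poor MCMC mixing: single-site Gibbs or random-walk updates move parameters
`θ` and latent variables `ξ` separately, so strong posterior correlation
between the two forces tiny steps and enormous chain lengths. **pbpmcmc**
implements *posterior-based proposals* (PBPs), a joint update scheme for any
model whose conditional dependence structure is a directed acyclic graph
(DAG): the latent process likelihood factorizes as

    π(ξ | θ) = ∏_e π(ξ_e | ξ_{e'<e}, θ),

with the nodes in topological order. It is aimed at statisticians and
quantitative biologists who write their own samplers — the benchmark models
come from veterinary epidemiology (latent-class diagnostic testing),
finance (stochastic volatility), quantitative genetics (the animal model)
and ecology (tau-leaping population dynamics).

## The method

One PBP update has three steps:

1. **Joint parameter jump.** Draw `θᵖ ~ N(θⁱ, j²Σ)`, where `Σ` approximates
   the posterior covariance of `θ` and `j` is a jump scale, both tuned
   during an adaptation phase and then frozen.
2. **Latent regeneration.** Walk the nodes in topological order. Each node
   carries an *importance distribution* (ID) `f_ID(ξ_e | ξ_{e'<e}, θ, y)`
   approximating its conditional posterior, with characteristic parameters
   evaluated at the initial state (giving e.g. a Poisson mean `λᵢ`) and at
   the proposed state (`λₚ`). A family-specific kernel then *modifies* the
   current value `ξ_eⁱ` into `ξ_eᵖ` — e.g. for Poisson IDs, add
   `X ~ Pois(λₚ − λᵢ)` when the mean rises and binomial-thin with
   probability `λₚ/λᵢ` when it falls. Kernels exist for eleven families
   (Poisson, normal, exponential, gamma, beta, Bernoulli, binomial,
   uniform, geometric, negative binomial, lognormal), each satisfying two
   conditions: they map the initial ID marginal exactly onto the proposed
   one (*marginal preservation*), and they return `ξ_eⁱ` unchanged as
   `θᵖ → θⁱ` (*identity limit*).
3. **Joint accept/reject.** Accept `(θᵖ, ξᵖ)` with probability

       P_MH = min{ 1, [π(y|ξᵖ,θᵖ) π(ξᵖ|θᵖ) π(θᵖ) / π(y|ξⁱ,θⁱ) π(ξⁱ|θⁱ) π(θⁱ)]
                      × ∏_e f_ID(ξ_eⁱ|·,θⁱ,y) / f_ID(ξ_eᵖ|·,θᵖ,y) }.

Because the latent state is dragged along with the parameter jump in a way
that respects the posterior's correlation structure, acceptance stays high
(targeted at 33%) for jumps that would be hopeless under single-site
updating. IDs form a hierarchy: **ID₀** is the model conditional itself
(the update is then a *model-based proposal*, MBP, and the ID ratio cancels
the latent likelihood ratio), **ID₁** folds in each node's own
observations, **ID₂** additionally folds in the observations of child
nodes. PBP blocks are interleaved with one standard Gibbs/random-walk sweep
every `U = 4` updates, and a pure standard sampler is available as a
baseline.

## Worked example

Infer disease prevalence and the performance of two imperfect diagnostic
tests without a gold standard, from one simulated cross-sectional survey of
1000 individuals (generating values: prevalence 0.5, sensitivities 0.6,
specificities 0.9):

```r
library(pbpmcmc)
scn <- diagnostic_scenario(P = 1000, p_D = 0.5, Se = c(0.6, 0.6), Sp = c(0.9, 0.9))
sim <- simulate_scenario(scn, seed = 1)
bm  <- build_diagnostic(scn, sim$data)       # model + exact per-individual ID1
trace <- run_chain(bm$model, bm$ids,
                   engine_config(updates = 20000, burnin = 5000, seed = 2))
summary(trace)
#> posterior summary (pbp_id1):
#>  parameter   mean      sd   q2.5 median  q97.5   ess
#>        p_D 0.3492 0.11812 0.1556 0.3417 0.5963 148.2
#>        Se1 0.7040 0.14029 0.5065 0.6796 0.9735 131.1
#>        Se2 0.7200 0.13611 0.5113 0.7036 0.9769 212.7
#>        Sp1 0.8397 0.07051 0.7390 0.8263 0.9873 225.9
#>        Sp2 0.8445 0.07593 0.7340 0.8304 0.9885 136.6
#> joint-proposal acceptance: 32.2%
```

Each row is a marginal posterior: mean, spread, central 95% credible
interval and effective sample size. All five generating values lie inside
their intervals — prevalence and test accuracies are only weakly identified
from two tests per individual, hence the wide intervals — and the joint
proposals were accepted at 32%, near the 33% adaptation target. Swapping
`bm$ids` for `NULL` runs the standard Gibbs baseline on the same model;
`make_id0(bm$model)` runs MBPs.

The same pattern works for the other benchmarks (`svt_scenario` /
`build_svt`, `mixed_scenario` / `build_mixed`, `logistic_scenario` /
`build_logistic`) and for user-defined DAG models assembled from
`pbp_param()`, `pbp_node()` and `pbp_obs()`. A command-line front end is
installed as `exec/pbpmcmc` (subcommands `simulate`, `run`, `diagnose`; see
`?run_cli`).

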