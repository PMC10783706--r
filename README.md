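# quietnet

Agent-based models of **opinion misperception** and the **spiral of
silence** in heterogeneous online communities.

## The problem

Online communities routinely misjudge how popular an opinion really is.
Two mechanisms can produce that distortion:

* **Exogenous (topological):** in scale-free networks the friendship
  paradox over-represents hubs in everyone's neighborhood, so whatever
  hubs express *looks* more prevalent than it is.
* **Endogenous (behavioral):** people who perceive local disagreement may
  misreport their view — or stop expressing it altogether — and each agent
  falling silent skews what its neighbors see, recruiting them into
  silence in turn.

`quietnet` simulates both mechanisms for the prototypical scenario of a
large consensus community infiltrated by a small, committed ("hard-core")
minority — think early anti-vaccination activists in a pro-vaccine
community.  Each agent *i* carries

* a fixed private belief *b\_i* = ±1 (the minority holds −1),
* a strength σ\_i ∈ (0, 1] (how firmly the belief is held), and
* a public expressed opinion ω\_i ∈ {−1, 0, +1}, where 0 is silence.

Agents live on a Molloy–Reed scale-free network, P(k) ∝ k^−λ with λ = 2.2,
minimum degree 2 and structural cutoff ⌊√N⌋.  The hard-core minority
(b = −1, σ = 1) is placed on every node of a chosen degree K\_c, so its
share of the population is P(K\_c) while its visibility grows with K\_c.

Two asynchronous dynamics are provided (one agent at a time, N updates =
one time unit):

* **Model 1 — majority conformity.**  The selected agent expresses its
  belief with probability σ\_i, otherwise it adopts
  sign(Σ\_{j∈Γ\_i} ω\_j), coin-flipping exact ties among neighbors who
  have spoken and staying null when nobody nearby ever has.
* **Model 2 — goal function with a silence option.**  The agent expresses
  the ω maximizing G(ω) = −|v − ω|, with anchor
  v = (σ\_i b\_i + Σ\_j A\_ij ω\_j)/(m + 1), influence weights
  A\_ij = deg(j)/deg(i), and m the number of non-silent neighbors (an
  alternative reading that normalizes only the social term is available
  via `parse = "social"`; see the methods vignette).  Hard-core agents
  always express −1.

The misperception observables are the population mean expressed opinion
⟨ω⟩, the local opinion climate r = ⟨Δ\_i⟩ with
Δ\_i = Σ\_{j∈Γ\_i} ω\_j / deg(i), and the decomposition
⟨b⟩ − r = (⟨b⟩ − ⟨ω⟩) − (r − ⟨ω⟩) into a behavioral and a topological
part, plus silencing statistics (silent agents per hard-core agent and
its power-law scaling in K\_c).

## Worked example

```r
library(quietnet)
set.seed(2024)
g <- generate_network(5000, 2.2)
g
#> <qn_graph> 5000 nodes, 12488 edges, degree range [2, 65]

pop <- assign_population(g, 3)     # hard core on every degree-3 node
hc_prevalence(pop)
#> [1] 0.1868

traj <- run_endogenous(pop, g)     # goal-function dynamics to stationarity
tail(tibble::as_tibble(traj), 3)
#> # A tibble: 3 × 6
#>       t mean_omega      r frac_plus frac_minus frac_silent
#>   <dbl>      <dbl>  <dbl>     <dbl>      <dbl>       <dbl>
#> 1    57      0.124 0.0623     0.354      0.230       0.417
#> 2    58      0.124 0.0627     0.354      0.230       0.416
#> 3    59      0.126 0.0639     0.355      0.229       0.415

fin <- final_population(traj)
misperception(snapshot(fin, g))
#> # A tibble: 1 × 3
#>   private_public_mismatch misperception topo_contribution
#>                     <dbl>         <dbl>             <dbl>
#> 1                   0.501         0.562           -0.0619

silenced_per_hc(fin)
#> [1] 2.223769
```

Although 81% of agents privately hold +1 (⟨b⟩ ≈ 0.63), only 36% still
express it at stationarity: 42% have been driven into silence and the
public mean opinion collapses to 0.13.  Almost all of that half-unit gap
between private belief and the perceived climate is behavioral
(`private_public_mismatch`); the purely topological part is an order of
magnitude smaller.  At K\_c = 3 each hard-core agent silences about two
others; sweeping K\_c shows this leverage growing roughly as K\_c^2
(`sweep_kc()` + `fit_silencing_scaling()`), so a vanishing, well-connected
minority mutes as many people as an abundant peripheral one.

Ensemble sweeps return tidy tibbles and plot directly:

```r
cfg <- model_config("endogenous", realizations = 100, seed = 1)
ens <- sweep_kc(cfg)          # one row per K_c, means and standard errors
autoplot(ens)
glance(fit_silencing_scaling(ens))
```

A thin command-line front end (`inst/cli/quietnet.R`) exposes
`simulate`, `sweep` and `fit` subcommands over the same functions.

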