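# repgame

An active-inference simulator for studying how **aberrant precision** can
produce psychopathy-like inference about the self. It is aimed at
computational-psychiatry researchers who want a small, fully testable
discrete-state model of the traits *lacks remorse* and *self-aggrandizing*.

## The model

A synthetic subject plays a 16-trial reputation game. Hidden states
factorize into **wealth** (8 levels, broke → wealthy) and **self-worth**
(charitable vs mean). Each trial the subject **donates** an offer (wealth
falls one level, charitable self-worth is sustained) or **keeps** it
(wealth rises one level, self-worth degrades), with a constant 10%
attrition of wealth. It observes its wealth exactly, plus a social
approval cue tied to self-worth with likelihood precision **α**:

$$P(\text{approval}\mid\text{charitable}) = \frac{e^{\alpha}}{e^{\alpha}+1}$$

so α = 0 gives an uninformative 50-50 cue and large α a near-identity
mapping. Choice-dependent self-worth transitions have prior precision
**β** ∈ (0, 1]: the action-disfavoured state persists with probability β,
so β = 1 de-couples self-worth from choices entirely and β = ½ is maximally
imprecise. Preferences (log prior over outcomes, C) rise log-linearly in
wealth and favour approval, both spanning 4 nats; they are never changed.

State inference is exact Bayesian filtering on the 16-state joint space;
actions minimize expected free energy
G = risk (KL from predicted to preferred outcomes) + ambiguity
(expected observation entropy), selected through a softmax with policy
precision γ = 8. Sweeping (α, β) maps regimes from altruism (precise α,
low β) to remorseless accumulation with preserved self-regard (α = 0,
β = 1). A companion module implements the closed-form precision-weighted
Gaussian self-appraisal model (posterior precision = sum of precisions,
posterior mean = precision-weighted average) with `undefended`,
`self_aggrandizing` and `lacks_remorse` presets.

## Worked example

```r
library(repgame)

# an altruist: precise social feedback, imprecise transition priors
summary(run_game(game_config(alpha = 4, beta = 0.55), seed = 1))
#> Reputation game (16 trials, alpha = 4, beta = 0.55)
#>   donations      : 94%
#>   final wealth   : level 1 (mean 1.06)
#>   P(charitable)  : 1.0000

# the psychopathy corner: uninformative feedback, frozen self-worth priors
summary(run_game(game_config(alpha = 0, beta = 1), seed = 1))
#> Reputation game (16 trials, alpha = 0, beta = 1)
#>   donations      : 0%
#>   final wealth   : level 8 (mean 6.50)
#>   P(charitable)  : 1.0000
```

The altruist donates almost every trial, stays broke (wealth level 1) and
maintains a high posterior of being charitable. With α = 0 the approval cue
carries no information, so wealth preferences dominate: the subject keeps
every offer and ends wealthy — and because β = 1 freezes self-worth
beliefs, its posterior P(charitable) remains 1.0 despite uncharitable
behaviour.

The staged developmental scenario chains the two impairments
(32 replicates; wealth carries across stages, self-appraisal re-anchors):

```r
developmental_trajectory(base_seed = 1, n_replicates = 32)
#>  stage alpha beta n_trials final_wealth mean_wealth p_charitable donation_fraction
#>      1     4 0.55       16         1.41        1.37      0.84425           0.84375
#>      2     0 0.55       16         7.94        6.60      0.00136           0.00195
#>      3     0 1.00       16         7.84        7.88      1.00000           0.00977
```

Losing likelihood precision (stage 2) yields wealth at the cost of
self-worth; subsequently raising prior precision (stage 3) preserves a
high self-worth posterior while the mean behaviour continues.

Other entry points: `run_sweep(sweep_grid())` for the full (α, β) heat-map
tables (`export_heatmaps()` writes them as long-format CSV with columns
`alpha, beta, metric, mean, sd`), `validate_model()` for structural checks,
`scenario("lacks_remorse")` for the Gaussian appraisal presets, and a CLI
(`exec/repgame`) with subcommands `run`, `sweep`, `trajectory`,
`appraisal`, `validate`.

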