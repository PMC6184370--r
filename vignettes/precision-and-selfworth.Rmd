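---
title: "Precision and self-worth: the model behind repgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision and self-worth: the model behind repgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgame)
```

## The scientific question

`repgame` asks how far two precision parameters alone can carry an account
of psychopathy-like inference about the self. A synthetic subject plays a
reputation game: on each trial it either **donates** an offer to charity or
**keeps** it. Donating sustains a *charitable* self-worth state, which in
turn solicits social *approval*; keeping accumulates *wealth* but erodes
self-worth. The subject prefers both being rich and being approved of. Its
pathology, when it emerges, is never a change of preferences — it is a
change in how confidently different parts of its generative model are
believed.

Two precisions are manipulated:

* **α (likelihood precision)** — how reliably the approval cue reflects the
  hidden self-worth state, mapped through a logistic bridge
  $P(\text{approval}\mid\text{charitable}) = e^{\alpha}/(e^{\alpha}+1)$.
  At $\alpha = 0$ the cue is 50-50 regardless of self-worth (prosocial
  feedback carries no information — the analogue of *lacks remorse*); as
  $\alpha \to \infty$ the mapping becomes an identity.
* **β (transition-prior precision)** — the probability that the
  action-disfavoured self-worth state persists for a trial. Donating keeps a
  charitable state with certainty and redeems a mean state with probability
  $1-\beta$; keeping is the mirror image. At $\beta = 1$ the transition is
  the identity for either action, de-coupling self-worth from choice (the
  analogue of *self-aggrandizing*, over-precise priors about the self);
  $\beta = 1/2$ is maximal imprecision, and below $1/2$ the parameter no
  longer acts as a precision, which is why default sweeps stop at $1/2$.

## The generative model

Hidden states factorize into wealth (8 levels by default, level 1 = broke)
and self-worth (charitable vs mean); the flattened joint index runs
wealth-fastest. Observable outcomes mirror the states: a wealth cue
(identity likelihood — the subject always knows how rich it is) and the
approval cue with precision α. Transitions are per-action column-stochastic
matrices: the wealth factor composes a deterministic shift (donate: one
level down with a floor; keep: one level up with a ceiling) with a constant
attrition that drops one level with probability 0.10 per trial, applied
after the shift (a configuration flag reverses the order for sensitivity
checks; the composition order is not dictated by the dynamics themselves,
only that both effects act once per trial). Log prior preferences rise
linearly across wealth levels and favour approval over disapproval, both
spanning 4 natural-log units by default. The initial prior is an exact
point mass on (broke, charitable).

Because the joint space is tiny (16 states), state inference is **exact
Bayesian filtering** — posterior ∝ prior × likelihood on the joint space —
rather than a variational message-passing scheme; at this scale the
variational fixed point and exact Bayes coincide, and exactness lets the
test suite compare the filter against brute-force enumeration of every
joint state trajectory (agreement to 1e-10 on games of length ≤ 4).

## Policy evaluation

Each trial the agent scores candidate action sequences (depth 1 by default,
configurable to 4 with exhaustive enumeration) by expected free energy

$$G(\pi) = \sum_{\tau,m}\; \underbrace{\mathrm{KL}\!\left[\,A_m q_\tau \,\Vert\, \sigma(C_m)\right]}_{\text{risk}} \;+\; \underbrace{\textstyle\sum_s q_\tau(s)\, H[A_m(\cdot\mid s)]}_{\text{ambiguity}}$$

where $q_\tau$ is the belief propagated through the transitions of the
policy, $\sigma(C_m)$ is the per-modality preference distribution obtained
by exponentiating and normalizing the log preferences, and $H$ is Shannon
entropy in nats. The policy posterior is a softmax of $-\gamma G$ with
policy precision $\gamma = 8$ by default; actions are sampled from it
(`selection_mode = "sample"`) or taken at its mode with ties broken in
favour of donating (`"argmax"`, used for deterministic tests). γ and the
selection rule are implementation choices the underlying account leaves
open; both modes are exposed.

## The environment

The generative *process* is distinguished from the generative *model*: the
manipulated α is the subject's confidence in prosocial feedback, so by
default the feedback itself is veridical (approval iff the true state is
charitable), while the true self-worth dynamics and attrition inherit the
agent's parameters. `share_with_model = TRUE` forces the environment to use
the agent's matrices verbatim. The wealth cue is noiseless, so no
model/environment mismatch can zero out wealth evidence; a floor of 1e-10
is mixed into the approval likelihood during updates so that an extreme α
cannot produce zero-evidence errors, and a genuinely impossible observation
raises an error rather than being silently renormalized.

## What the sweep shows

`run_sweep()` simulates 32 independent 16-trial games per cell on a default
grid of 17 α values (0–4) × 11 β values (0.5–1), summarizing each cell by
the replicate-averaged final-trial posterior P(charitable) and final true
wealth level (a time-averaged wealth metric is also recorded). Grid ranges
and cell summaries are design choices: the α range spans the 50-50 to
~98%-veridical regimes, the β range spans the interval in which β acts as a
precision, and "final trial" summaries were fixed once alongside the
default γ, preference span and replicate count so that the four directional
corner regimes hold, then frozen; the scientific claim is the directional
pattern, not particular cell values. Per-cell replicate seeds derive
deterministically from the base seed and cell index, so results are
invariant to evaluation order.

The pattern that emerges: precise-α, low-β subjects donate and stay poor
but charitable (altruists); dropping α to 0 makes prosocial feedback
uninformative, so wealth preferences dominate and subjects accumulate
wealth while — at low β — their inferred self-worth collapses; raising β
toward 1 then freezes self-worth beliefs, so the α=0, β=1 corner
accumulates wealth *and* retains a high posterior of being charitable: the
psychopathy corner. Among precise-likelihood cells (α ≥ 2) wealth and
self-worth rank-anticorrelate.

## The developmental trajectory

`developmental_trajectory()` chains three epochs — (α=4, β=0.55) →
(α=0, β=0.55) → (α=0, β=1.0), 16 trials each — mirroring an acquisition
sequence: first prosocial feedback is discounted, then prior precision
rises. Material circumstances persist across epochs: the true wealth level
and the wealth belief carry over (`carry = "wealth"`, the default). The
self-worth state and belief, by contrast, re-anchor on the charitable
initial prior at each epoch onset, so each epoch reports the self-appraisal
equilibrium its precision regime supports — the same quantity the sweep's
heat map reports for that (α, β) cell. This choice is deliberate: with full
carry-over (`carry = "all"`, also available) a belief that collapsed in
epoch 2 can never recover in epoch 3, because at α=0 the approval cue
carries no information and keep-dominant behaviour only degrades (β < 1) or
freezes (β = 1) the self-worth belief — the third epoch would then show
preserved-but-low, not restored, self-worth, which is not the regime
comparison the staged scenario is meant to read out. `carry = "none"`
restarts everything each epoch.

## The Gaussian appraisal model

Alongside the discrete game, a one-dimensional conjugate Gaussian model
captures precision-weighted self-appraisal directly: beliefs over a valence
scale (negative = shame/worthlessness) are fused exactly,
$\tau_{post} = \tau_p + \tau_l$,
$\mu_{post} = (\tau_p\mu_p + \tau_l\mu_l)/\tau_{post}$. Three presets on a
valence scale of roughly [−2, 2] realize the qualitative regimes:
*undefended* (weak positive prior μ=0.5, τ=1 vs precise negative evidence
μ=−1.5, τ=4 → negative posterior), *self-aggrandizing* (elevated,
over-precise prior μ=1.5, τ=16 → positive posterior despite the same
evidence) and *lacks remorse* (neutral prior vs attenuated evidence
τ=0.05 → near-zero posterior). The preset numbers and the ±0.25 neutral
band of `classify_valence()` are conventions, exposed as arguments rather
than hard-coded truths; only the qualitative labels are asserted.

## Numerical and degenerate-input choices

* Stochastic-matrix invariants are enforced to 1e-12; `validate_model()`
  reports violations by component and column.
* Policy posteriors subtract the maximum before exponentiating, so they are
  invariant to adding a constant to all G values and safe for large γ.
* A zero-probability observation raises an error (surfacing
  model/environment mismatch) instead of silently renormalizing.
* `horizon = 0` games return an empty trial table flagged `empty`, with
  summary metrics equal to the initial conditions.
* Seeds are 32-bit integers; all derived seeds stay below 2^31.

## Problem sizes and what passing tests show

The test suite exercises the default sweep (17 × 11 cells × 32 replicates
of 16-trial games), 32-replicate staged scenarios, brute-force filtering
oracles on games of length ≤ 4, and 100,000-sample Monte-Carlo checks of
the attrition rate — sizes chosen so the full suite completes in about a
minute while keeping replicate noise well below the directional effects
being asserted. The synthetic environment is the model's own world: cues
are conditionally independent given the true state, feedback is veridical,
and preferences are stationary. Passing tests therefore show that the
implementation realizes this idealized game faithfully — not that human
social feedback, real reputational dynamics, or clinical traits behave this
way. No parameters are fit to data; mapping the valence scale or the
precision parameters onto clinical instruments is out of scope.
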