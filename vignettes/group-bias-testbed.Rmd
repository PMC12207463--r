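---
title: "A desk-scale testbed for emergent in-group bias in learning agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale testbed for emergent in-group bias in learning agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

groupsim simulates a population of 8 "red" and 8 "blue" reinforcement-learning
agents playing a partially observable Markov game on a 2-D grid. The game is a
coordination-foraging task: colored resources (red, green, blue — unrelated to
the agent colors) stochastically populate fixed resource points; an agent that
walks over a resource collects it into a length-3 inventory and acquires a
translucent "ready to interact" headband. An agent can fire a short
interaction beam (straight line along its heading, range 3 cells, blocked by
walls); when the beam connects with a ready partner, both participants receive
the same reward,

r = inv_i . inv_j,

the dot product of the two inventories. Both then freeze in place for 16 steps
and disappear for 50 steps before respawning with an empty inventory. Episodes
last between 1,000 and 5,000 steps (drawn uniformly at reset in the reference
configuration). Avatar color carries no reward information whatsoever — the
payoff structure is completely symmetric in the group labels — so any
systematic color preference that appears in behavior is an emergent bias.

Episodes are scheduled on two servers. The *in-group server* samples all 8
members of one population (chosen by a fair coin), so every partner an agent
meets there shares its color. The *mixed server* samples m members from a
(uniformly chosen) majority population and n from the other, without
replacement, at a ratio m:n varied across conditions from 8:0 to 4:4. Under a
per-episode coin flip between servers, each agent's long-run expected share of
in-group-server episodes is 1/2. Differential familiarity with the two colors
is therefore an experimental dial: at 8:0 an agent never meets the other
color; at 4:4 exposure is symmetric.

## Observations and agents

Each agent sees an egocentric window of 11×11 sprites (5 to each side, 9
forward, 1 back), rotated so its heading points up. Sprites are 8×8 RGB
tiles, giving an 88×88×3 pixel observation; the inventory vector is passed
alongside. The reference policy network is a two-stage convolutional encoder
(16 channels, kernel and stride 8 to match the sprite raster; then 32
channels, 4×4 kernel, stride 1), the inventory concatenated to the flattened
encoder output, a 2-layer 64-unit ReLU trunk, an LSTM core of 256 units, and
256-unit policy and value heads with linear outputs over the 8 actions
(movement, turning, strafing, no-op, beam). Every agent owns a private
network; there is no parameter sharing and no learning signal crosses agents.

Training is synchronous advantage actor-critic: discounted returns with
bootstrapping, advantage = return − value, an entropy bonus (weight 0.003),
a value-regression term, and RMSprop (lr 4e-4, epsilon 1e-5, momentum 0,
decay 0.99) on truncated 100-step segments. A truncated importance-weighting
correction (per-step likelihood ratios clipped at 1, applied to both the
value-target recursion and the advantage) is available behind
`training_config(vtrace = TRUE)` for off-policy replay; with on-policy
synchronous rollouts it reduces exactly to the plain advantage estimator, so
the default keeps it off. Auxiliary representation losses and adaptive return
normalization used in large distributed setups are out of scope here; the
learner is deliberately the plain algorithm.

All forward and backward passes are written explicitly in R (dense, conv via
im2col, GRU and LSTM back-propagation through time). The test suite validates
every architecture variant against finite-difference gradients of a surrogate
objective computed through the public forward pass only.

## Measuring bias: the dual-choice probe

Bias is measured outside the training environment. At a fixed cadence a
frozen snapshot of each probed agent (6 per group by default; 4 in the
individuation experiments) is placed in a small resource-stocked room
(7×9) with exactly two immobile, always-ready target sprites at positions
re-randomized every episode. The episode ends when the evaluated agent's beam
connects with one target, or after 1,000 steps (recorded as undecided, and
excluded from ratios but counted). For the group-bias probe the targets are
one generic (pixel-free) sprite per group color; the per-agent *in-group
choice ratio* is the fraction of decided episodes choosing the same-color
target, binned over training steps (bin width six times the evaluation
cadence, preserving the reference 5M:30M ratio), and the group value is the
average of the per-agent averages. The *group bias* of a bin is

bias = (ratio_red + ratio_blue) / 2 − 0.5,

zero at chance and 0.5 when both groups always choose their own color. The
published account describes this quantity only as the gap between the two
group curves together with its 0–0.5 range; the halved-gap form above is the
one definition consistent with both statements, and alternative summaries can
be built directly from the returned per-agent table. Summed bias adds the
per-bin values over a complete series (missing bins are an error, never
interpolated).

In the training environment itself, interaction events are categorized as
majority-on-majority, minority-on-minority, or mixed, and their percentage
shares are divided by the chance weights m(m−1)/D, n(n−1)/D and mn/D with
D = m(m−1) + n(n−1) + mn. At 6:2 these weights are exactly 30/44, 2/44 and
12/44. Note the deliberate asymmetry of the convention — within-group pairs
are counted ordered, the cross pair unordered — because that is the convention
under which the published fractions are exact; the weights always sum to 1 and
a normalized value of 1 means "at chance given the group sizes".

For the individuation experiments (always run at 7:1), every member carries a
unique one-pixel marker at sprite coordinate (4,4); one member per population
is "less desirable": its personal freeze duration is elevated (16 steps for
everyone else; the sweep uses {16, 24, 32, 48, 64, 96, 128}), and an
interaction freezes *both* partners for the maximum of their personal
durations. The discrimination probe offers a same-color pair — one generic
sprite, one bearing the marked agent's pixel — and scores the fraction of
decided episodes avoiding the mark, separately for targets drawn from the
agent's own and the other group; the in-group minus out-group difference is
the individuation gap. The bright pixel variant is [255,255,0], the dark
variant [80,80,0]; neither value is prescribed anywhere, only "bright" versus
"duller", so these are package choices.

## Scale presets

Three presets share identical game rules and differ only in scale:

* `paper`: the reference architecture above, 100-step unrolls in batches of
  252 from ~1,000 parallel environments. Provided for fidelity; far beyond a
  single CPU.
* `desk`: pixel observations with a 32+32 trunk and GRU-64 core, batch 32.
* `micro`: the compact symbolic observation (below) with a feedforward
  32+32 trunk, used by the shipped experiment configs and the scaled-down
  emergence checks.

The symbolic observation is an 18-vector: own ready flag and inventory;
(presence, forward, lateral) triples for the nearest visible resource, the
nearest visible ready agent of population slot 1, of slot 2, and the nearest
non-ready agent, all in egocentric coordinates clipped to the same 11×11
window the renderer draws; and one beam-alignment indicator per population
slot (a ready agent of that slot stands straight ahead within beam range —
exactly the alignment a convolutional encoder reads off the pixel raster).
Slots are keyed by global population order — not by the observer's own
group — and the two slots are represented identically, so the representation
is exactly as group-symmetric as the pixels: any color preference must still
be learned from experience. The pixel pipeline itself (rendering, conv/LSTM forward and
backward, probes) is exercised end to end by the unit tests; the micro preset
exists because training five replicates of four conditions of 16
pixel-policies is not a single-CPU job, and the exposure mechanism under
study operates on which partners an agent *meets*, which the symbolic view
preserves faithfully.

Micro-scale optimization deviates from the reference constants in two
documented ways, chosen once when the preset was designed: the learning rate
is raised (tiny networks, tiny batches) and the discount is lowered to 0.9.
The latter matters: with γ = 0.99 and the short episodes of the micro preset,
every action within ~50 steps of a reward receives nearly equal credit, which
empirically washes out feature-conditioned behavior in favor of unconditional
action priors; γ = 0.9 concentrates credit on the approach-and-fire segment
that actually caused the interaction while still spanning the ~20-step
approach horizon.

## Numerical and design choices

* Reward proportionality constant is 1 (only proportionality is specified);
  configurable via `reward_scale`.
* Both participants must be ready for an interaction to fire
  (`require_initiator_ready = TRUE`): the published description requires it
  only of the target, but the schematic shows both choice partners wearing
  headbands, and without the flag an empty-inventory agent could harvest
  reward from others' inventories. The flag also governs whether the probe
  agent must collect a resource before it can choose.
* Beam: straight line, range 3, first agent hit, blocked by walls; no beam
  geometry is published.
* Simultaneous moves resolve in randomized agent order; moves into occupied
  or wall cells are no-ops. Beams resolve after movement, also in randomized
  order; an agent frozen earlier in the same step loses its queued beam.
* Episode length: uniform integers on the configured range (the reference
  source gives only the 1,000–5,000 interval).
* Restocking: each empty resource point restocks per step with probability
  0.005 (reference) — the shipped micro configs raise this to 0.05–0.1 so
  short episodes still contain interactions; color uniform over the enabled
  colors; the single-resource control enables one color.
* Respawning clears inventory and ready flag (unstated in the source;
  unbounded inventories otherwise) and draws a free spawn point uniformly,
  honoring per-color restrictions in the wall and eight-cell layouts.
* Probe targets are flagged non-acting and given inventory (1,1,1), so they
  satisfy the ready-implies-nonempty-inventory invariant and a probe
  interaction pays the evaluated agent its own inventory sum.
* All stochasticity flows from one master seed through named substreams
  (scheduler, episode, init, probe, ...), so runs are bit-reproducible and
  adding probe episodes does not perturb the training stream.
* Undefined statistics are surfaced, never imputed: zero decided episodes in
  a bin flags the bin, zero total events makes chance normalization an error,
  and zero variance makes the correlation an error.

## What the synthetic scale does and does not show

The micro preset reproduces the *mechanism* under study — asymmetric exposure
shapes which approach behaviors are reinforced — with networks of a few
thousand parameters and runs of tens of thousands of steps, versus hundreds
of millions at reference scale. Quantities that depend on representation
learning from pixels (the visual-similarity sweep over purple pairs, pixel
individuation) have shipped configurations and a fully implemented pixel
pathway, but their headline effects should not be expected to reach
reference-scale magnitudes under micro budgets, and the package's acceptance
checks therefore assert analytic identities, scripted-policy oracles and
qualitative orderings rather than published effect sizes. Inferential
statistics (ANOVAs, t tests, multilevel models) are out of scope: the metric
tables are exactly the per-cell inputs such tests consume.

## Problem sizes used by the shipped checks

The emergence checks in the test suite run five seeded replicates of four
micro-scale conditions (8:0, 4:4 and 6:2 on the open 9×9 arena, and 6:2 on
the eight-cell layout): 4,500 training episodes of 100–140 steps each for
the 8:0/4:4 comparison (roughly 540,000 environment steps per condition —
past the ~300,000-step onset of the 8:0 bias), 3,000 episodes for the 6:2
decline check and 2,400 for the eight-cell run, with dual-choice probes of
20 episodes per snapshot every 6,000 steps, binned at 36,000 steps. Unit tests use far smaller boards and
scripted policies; the acceptance script estimates the random-walk chance
ratio over 500 decided dual-choice episodes. These sizes are the package's
choices for a reproducible single-CPU run and are archived in each run's
manifest.

One consequence of the scaled horizon is worth stating plainly: within
~360,000 steps the never-exposed (8:0) condition develops a clear in-group
bias while the symmetric (4:4) and forced-mixing (eight-cell) conditions stay
at chance, but in the *partially* exposed conditions (7:1–5:3) the bias is
still growing at the end of the run. The eventual decline of bias under
continued exposure — the contact-effect signature — requires horizons several
times longer than the shipped suite's; the suite's decline check therefore
documents this limitation of the scale rather than the phenomenon, and longer
runs with the same configuration objects are the way to study it.
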