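---
title: "The geometry of two-party evolutionary conflict: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geometry of two-party evolutionary conflict: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomconflict)
```

## The model

Fisher's geometric model treats the phenotype as a point $z$ in an
$n$-dimensional trait space, mutation as a random jump, and a mutation as
beneficial if and only if it lands strictly closer to the optimum. In the
origin–fixation regime adopted here, every beneficial mutation is certain to
fix, so the unit of simulated time is the *invasion event*: the appearance
and fixation of one beneficial mutation.

`geomconflict` extends this picture to two agents, A and B, with distinct
objective points $\mathbf{a}$ and $\mathbf{b}$. Each incoming mutation is
*governed* by agent A with probability $p$ and by agent B otherwise, and is
accepted iff it is beneficial *for its governor*. The two parties therefore
take turns — stochastically, with weights set by the balance of power $p$ —
dragging a single shared phenotype toward their own optimum. The derived
distance $d = \lVert \mathbf{a}-\mathbf{b} \rVert$ is the natural unit of
every maladaptation statistic.

Assumptions inherited from the classical model and kept here:

* the phenotype space is finite (an axis-aligned box; see below);
* every point is mutationally connected to every other, and all mutations
  are equally likely — proposals are uniform over the box (fully
  pleiotropic mode) or uniform along one uniformly chosen axis (fully
  modular mode);
* acceptance is strict: an exact distance tie is not beneficial;
* beneficial mutations fix with certainty (no drift, no selection
  coefficients, no segregating variation).

Two objective modes are supported: optimum-seeking (beneficial = strictly
closer) and pessimum-avoiding (beneficial = strictly farther from the point
where an agent's agenda is most poorly realized).

## The phenotype space is a box, and it matters

The underlying theory only requires the space to be finite but arbitrarily
large. We realize it as a continuous axis-aligned box with uniform proposal
measure — the continuum limit of a dense finite lattice — with default
half-width $10d$ per axis, centred so the optima sit at $(\mp d/2, 0,
\dots, 0)$ and the initial phenotype at their midpoint. Occupancy statistics
depend on the box extent (a larger box dilutes the battleground), so the
half-width is an explicit, reported parameter of every configuration rather
than a hidden constant.

One experiment deliberately deviates: the pessimum-avoidance scenarios use a
default half-width of $1d$. With pessima at $\pm d/2$, a box comparable in
scale to their separation puts each agent's most-distant (least-worst)
boundary point next to the rival's pessimum, which is precisely the regime
in which two disagreeing agents hold the phenotype close to both pessima. In
a box ten times wider, both agents' least-worst corners are far from both
pessima, the equilibrium ping-pongs between the box ends, and near-pessimum
occupancy vanishes for a reason that has nothing to do with the single-agent
escape result the scenario is contrasted with (we verified this directly:
with half-width $10d$ the disagreeing-agents final-window occupancy is
0.000; with half-width $1d$ it is roughly 0.2 near each pessimum).

## Conflict intensity, exactly and by Monte Carlo

The intensity of conflict at a phenotype $z$ is the probability that the
*next beneficial mutation* — whichever agent governs it — is beneficial only
for its governor and strictly deleterious for the other agent. Because
governors are drawn per proposal, the governor of the next *accepted*
mutation is A with probability

$$w_A \;=\; \frac{p\,m_A}{p\,m_A + (1-p)\,m_B},$$

where $m_g$ is the measure of agent $g$'s beneficial set: the weighting is
by the chance that a proposal is governed by $g$ *and* beneficial, not by
$p$ alone. With $c_g$ the measure of the part of $g$'s beneficial set that
is strictly deleterious for the rival, the intensity is $w_A c_A/m_A + w_B
c_B/m_B$.

In one dimension every beneficial set is an interval union — a ball around
the optimum clipped to the box, or the complement of a ball around the
pessimum — so `conflict_intensity_1d()` evaluates the statistic by exact
interval arithmetic. The same kernels give
`next_mutation_inside_outside_1d()`, the exact split of the next accepted
mutation between the open battleground interval and its exterior. Two exact
consequences are worth stating:

* the intensity equals 1 exactly on the open segment between the optima and
  declines monotonically beyond either optimum;
* the *outside* probability is at least as large as the *inside*
  probability for every phenotype and every $p$ — the next invasion is at
  least as likely to land outside the zone of conflict as within it
  (hyper-maladaptation).

In higher dimension the beneficial sets are balls intersected with the box
and no closed form is attempted (a deliberate non-goal);
`conflict_intensity_mc()` estimates the same conditional probability from
uniform proposal draws, with a Bernoulli standard error over the beneficial
draws, and is cross-checked against the exact 1D kernel in the test suite.

## Two equivalent dynamics engines

`invasion_step()` is defined as a literal propose/reject loop: draw a
governor, draw a proposal, repeat until one is beneficial for its governor.
The `"rejection"` engine implements exactly that, in batches that consume
the RNG stream in the same order as one-at-a-time draws (per proposal: one
governor uniform, then the proposal uniforms — $n$ coordinates in
pleiotropic mode; axis then coordinate in modular mode). The loop is
bounded by `max_proposals`; exceeding it raises an `"absorbed"` error that
carries the stuck state, rather than looping silently.

The literal loop is, however, computationally impossible exactly where the
model is most interesting. A pleiotropic proposal is accepted with
probability $\mathrm{vol}(\text{ball} \cap \text{box}) /
\mathrm{vol}(\text{box})$, which at $n = 16$ dimensions and the default box
is of order $10^{-14}$: the published endpoint design (100 events × 500
replicates over $n \in \{1,2,4,8,16\}$) would need $\sim 10^{18}$ proposals.
The `"direct"` engine therefore samples the *outcome* of the loop from its
exact conditional law instead: the accepted mutant is uniform on the
governor's beneficial ball intersected with the box; the governor of the
accepted mutation is A with probability $w_A$ above; and the number of
proposals consumed is geometric with success probability $(p\,m_A +
(1-p)\,m_B)/\mathrm{vol}(\text{box})$, drawn by inverse CDF in doubles so
that astronomically long waits are represented without integer overflow.
Ball measures are computed in closed form when the ball lies inside the box
and otherwise corrected by a small Monte Carlo clip-fraction estimate (128
draws; rare under the default geometry). The two engines agree in
distribution, which the test suite checks directly.

The `"auto"` engine uses the direct sampler for pleiotropic optimum-seeking
models in two or more dimensions, and also in the single-party limits $p \in
\{0, 1\}$, where the rejection loop's acceptance probability halves with
every event (the beneficial ball shrinks geometrically) and the proposal
budget is exhausted after a few dozen events. Everything else — 1D conflict,
modular mutation, pessimum avoidance — runs the literal loop.

Two numerical facts about the single-party limit deserve a note. First, the
distance to the governing optimum halves per event, so after about 50 events
the phenotype reaches the optimum *at double precision* and the state is
genuinely absorbed (no strictly beneficial mutant is representable);
`run_dynamics(..., on_absorbed = "truncate")` returns the recorded prefix
for callers that expect this. Second, close to the floor, rounding can
repeat a distance exactly, so strict monotone convergence is only asserted
above $10^{-12}$.

Sampling is performed in normalized unit coordinates and affinely mapped to
the box (and, in the direct engine, ball measures are computed relative to
the box volume). Multiplying all bounds, objective points and the initial
phenotype by $c = 2$ with a matched seed therefore reproduces every recorded
phenotype exactly doubled, bit for bit — the testable form of the statement
that all equilibrium distances are directly proportional to $d$.

## Long-run summaries

`maladaptation_summary()` reports the mean Euclidean distance of the
phenotype from the *governing objective* — per record, the objective of the
agent that governed that invasion — per dimension, overall, and per agent,
after discarding a burn-in (default: the first half of the events; no
mixing-time analysis is attempted, and the window is configurable).

Two weightings are computed throughout. *Event* weighting gives each
invasion snapshot equal weight — the archaeological record of fixations.
*Proposal* weighting weights each post-invasion state by its sojourn, the
number of proposals drawn until the next invasion (the final state's sojourn
is right-censored and is dropped, which is unbiased for the stationary law)
— the state of the population between invasions. The distinction is *not*
always qualitative garnish: battleground states have the smallest beneficial
sets and hence the longest sojourns, so in the canonical 1D model the
event-weighted probability of sitting inside the battleground is about 0.43
while the proposal-weighted probability is about 0.57. The
hyper-maladaptation occupancy claim — outside at least as likely as inside —
is a statement about where invasion events land, and is asserted
event-weighted; both numbers are reported.

Standard errors for all trajectory averages use a circular moving-block
bootstrap (default block 100 events, 200 resamples), because invasion
snapshots are strongly autocorrelated and i.i.d. errors would be
overconfident. Replicate-based experiments use plain across-replicate
standard errors.

`scaling_fit()` is an ordinary least-squares fit of $\log(\text{mean})$ on
$\log(n)$; the slope is the cost-of-complexity exponent (0.5 = square-root
growth, 0 = no cost). It requires at least three distinct $n$ and positive
means.

## The endpoint scaling statistic

The dimensionality experiments reproduce the published endpoint design: for
each $n$, 500 independent replicates of 100 invasion events, summarized at
the endpoint. Two conventions for "distance from the governing optimum"
coexist here, and the package is explicit about which is used where:

* the **overall** statistic is the expected distance from the optimum
  governing an *incoming* mutation, $p\,\mathrm{dist}_a + (1-p)\,
  \mathrm{dist}_b$ — at $p = 1/2$, the distance from each party's optimum,
  the quantity the midpoint ($d/2$) and capitulation ($d$) benchmarks refer
  to. Conditioning instead on the governor of the *final recorded* invasion
  would bias the distance low (that invasion just moved the phenotype into
  its governor's beneficial ball) and inflate the fitted exponent from
  $\approx 0.48$ to $\approx 0.62$;
* the **per-dimension** statistic keeps the invasion-snapshot convention
  (deviation from the recorded governor's objective, averaged over
  coordinates), the within-dimension maladaptation experienced under the
  agenda that actually governed the event.

Under full pleiotropy the per-dimension statistic is approximately constant
in $n$ (measured exponent $\approx 0.04$) while the overall statistic grows
approximately as $\sqrt{n}$ (measured exponent $\approx 0.48$): a
conflict-driven cost of complexity. The geometric mechanism is visible in
the engine itself: each accepted state is uniform in a ball centred on the
governing optimum, so its per-coordinate deviation is $\sim r_n/\sqrt{n}$
while its overall distance is $\sim r_n$; a constant per-coordinate
deviation forces $r_n \propto \sqrt{n}$.

Under full modularity, axes on which the two objectives agree can only
improve: any accepted mutation on such an axis is beneficial for both
agents, per-axis deviation is non-increasing along the whole trajectory
(exactly, and tested exactly), and the conflict axis behaves as the 1D
model — so the overall cost of complexity disappears (measured exponent
$\approx 0.02$). The modularity experiment demonstrates the convergence on
a 2D run started with the uncontested axis displaced by $d$ (after $10^4$
events the deviation is $\sim 10^{-4} d$), and compares the conflict-axis
marginal of a long 2D modular run against a matched 1D run on common bins.

## The balance of power, pessima, and compromise

`exp_p_sweep()` measures, across a grid of $p$, the same overall
maladaptation statistic as the dimensionality experiments: the
event-weighted mean distance from the optimum governing an incoming
mutation, $p\,\mathrm{dist}_a + (1-p)\,\mathrm{dist}_b$. It vanishes at
$p \in \{0, 1\}$ (Fisher's limit) and is maximal at even control,
$p = 1/2$ (about $0.77d$, against $0.76d$ at $p = 0.4$ or $0.6$). The true
curve is flat near the peak, so resolving the literal argmax at the
published run length ($2 \times 10^4$ events per grid point, standard
error $\approx 0.005d$) remains a near-tie comparison with residual seed
noise; the driver reports the full table with block-bootstrap errors
alongside the argmax, and the decline toward the extremes (by $\sim
0.17d$) is the robust signal.

`exp_pessima()` contrasts three pessimum-avoiding scenarios (single agent;
two agents with pessima at $\pm d/2$; two agents sharing one pessimum) via
windowed occupancy of $\varepsilon$-balls (default $\varepsilon = 0.25 d$)
around both pessima. A single avoider's distance from its pessimum
increases monotonically, so its beneficial measure shrinks geometrically
and the run hits the proposal budget after a few dozen events, pinned at
the boundary; the experiment treats the post-absorption phenotype as frozen
and pads the remaining windows with it (occupancy 0 near the pessimum, the
correct continuation). Two disagreeing agents keep invading forever and
hold roughly 20% of final-window mass near each pessimum.

`exp_compromise()` puts the conflict in game-theoretic units: the long-run
mean distance from each optimum under conflict exceeds $d/2$ in 1D (both
parties would do better agreeing on the midpoint) and exceeds $d$ from two
dimensions up (each party would do better capitulating outright). The
myopic side of the ledger is computed exactly in 1D from the interval
kernels: the expected own-optimum distance after the next invasion, with
the agent participating versus relinquishing all governance to the
adversary. Participating is strictly better for every current phenotype
closer than $d$ beyond the adversary's optimum, with exact equality at
$z = b + d$ — and, a finding worth flagging, the comparison *reverses*
beyond that point: a hyper-maladapted agent far past its rival's optimum
has a beneficial set so large and symmetric about its own optimum that its
mean improvement is poorer than the rival's agenda would deliver (the
familiar inefficiency of large mutations, in conflict clothing). Short of
that extreme region, neither party is myopically favoured to quit, which is
how mutually ruinous long-run conflict persists.

## Reproducibility discipline

Every trajectory is a deterministic function of its configuration
(including the seed); every experiment is a deterministic function of its
configuration and root seed, with per-replicate seeds drawn once from the
root. Governor draws consume the stream before mutant draws, batches
consume it in one-at-a-time order, and the direct engine's draw order
(governor, geometric count, ball point) is fixed — so oracles can replay
any run. Output tables carry a configuration hash, the seed, and the
package version in a JSON manifest, and re-running a configuration
overwrites its outputs byte-identically.

## Problem sizes

The shipped defaults mirror the published study designs: $1.5 \times 10^5$
invasion events for the 1D equilibrium, 100 events × 500 replicates for the
dimensionality sweeps over $n \in \{1, 2, 4, 8, 16\}$, $2 \times 10^4$
events per grid point for the power sweep, $2 \times 10^4$ events per
pessima scenario, and $10^5$-event long runs for the compromise accounting.
On one CPU the full set runs in a few minutes. The package's own unit tests
use smaller versions of the same designs; the full designs are exercised in
the acceptance suite.

## What the simulations do and do not show

The generator *is* the model: uniform mutation over a bounded continuum,
two agents, certain fixation. Passing tests establish the geometry of
conflict under those idealizations; they say nothing about mutation kernels
with local steps (Fisher's small-step analysis is deliberately not
reproduced), population-genetic fixation probabilities, more than two
agents or coalition formation, correlated mutational effects between the
pleiotropic and modular extremes, or any particular biological system. The
box realization of "finite but arbitrarily large" is a stand-in; occupancy
statistics depend on its extent, which is why it is a reported parameter
everywhere, and why the pessima experiment's box scale is a documented,
deliberate choice.
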