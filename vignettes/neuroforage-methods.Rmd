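---
title: "Diffusion-based neuromodulation on a seasonal foraging task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based neuromodulation on a seasonal foraging task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroforage)
```

`neuroforage` simulates small, spatially embedded feed-forward neural
networks that must learn, within their lifetime, which food items are
safe to eat in each of two alternating seasons — a diagnostic problem
for *catastrophic forgetting*: does learning the winter associations
erase the summer ones?  The package implements the whole experimental
loop: the foraging environment, two neuromodulated Hebbian learning
rules (wire-borne and diffusion-based), multi-objective neuroevolution
of the networks, the seasonal-retention metrics, and the Activation
Record Knockout (ARK) analysis that prunes a trained network down to a
core functional network (CFN) whose connections can be attributed to
the summer task, the winter task, or both.

## The network model

Networks are layered, strictly feed-forward, weighted digraphs in which
every node has a position in the plane.  The default topology has
layers of 5, 12, 8, 6 and 2 nodes placed at y = 4 (inputs) down to
y = 0 (outputs), nodes centred on x = 0 at unit spacing — 33 nodes, and
216 connections when adjacent layers are fully connected.  A non-input
node activates as

$$a_i = \phi\Big(\sum_{j \in C_n} w_{ij} a_j + b_i\Big), \qquad
  \phi(x) = \frac{2}{1+e^{-32x}} - 1,$$

where $C_n$ are its non-modulatory in-neighbours and $b_i$ its bias.
The slope of 32 makes $\phi$ nearly a step function, so activations are
usually close to ±1; input nodes pass their values through unchanged.
Mutations may create connections that skip layers; lateral and
recurrent connections never exist.  We treat "fully connected" at
initialisation as adjacent-layer connectivity; both choices are
configurable in `network_config()`.  Only hidden nodes can take the
modulatory role under the wire-borne rule: inputs carry task data
verbatim, and a modulatory output could never be read, so restricting
the role to hidden nodes changes nothing that is observable while
keeping the semantics of the two special layers clean.

## The foraging task

Food items are the eight 3-bit vectors over {−1, +1}.  An
*environment* fixes, for each season, a decision bit (uniform over the
three) and a polarity (uniform over ±1): an item is nutritious iff its
decision bit equals the polarity, so each season splits the items
4/4.  A lifetime is three years of a 5-day summer and a 5-day winter;
every day presents all eight items in a fresh random order — 240
presentations.  Inputs 1–3 carry the current item; input 4 (summer)
and input 5 (winter) carry the *seasonal feedback*: +1/−1 if the
previously presented item was eaten and was nutritious/poisonous, and 0
otherwise, always 0 out of season and at the first step of a season.
The agent eats when the season's output exceeds 0 (left output in
summer, right in winter; an output of exactly 0 means "do not eat").
Fitness is

$$F = 0.5 + \frac{\#\text{nutritious eaten} - \#\text{poisonous eaten}}
  {\#\text{total food}},$$

so never eating scores 0.5, indiscriminate eating also scores 0.5, a
policy that implements exactly one season's rule scores 0.75 over a
full lifetime (when the two rules use different decision bits), and a
dual-rule policy scores 1.  These closed-form anchors are asserted
exactly in the test suite and recomputed by `scripts/acceptance.R`.

The environment generator is the package's synthetic-data module: it
emulates the study conditions exactly (3-bit foods, uniform rules,
within-day exhaustive presentation without replacement, 3 × 2 × 5-day
lifetimes).  It does not emulate anything beyond them — there is no
sensory noise, no partial observability, and the rules are stationary
within a lifetime — so passing tests speak to the model system, not to
noisy real-world learning problems.

## Learning rules

Both rules share the modulated Hebbian update
$\Delta w_{ij} = \eta\, m_i\, a_i\, a_j$ with $\eta = 0.002$, applied to
every connection into a regular (non-modulatory, non-input) node.
Under **standard neuromodulation** the modulatory signal is wire-borne:
$m_i = \phi(\sum_{j \in C_m} w_{ij} a_j)$ over connections from
modulatory nodes, and exactly 0 for nodes without modulatory
in-neighbours.  Under **diffusion-based neuromodulation** there are no
modulatory nodes; two point sources at (−3, 2) and (3, 2) emit a
simulated chemical whose steady-state concentration at distance $d$ is

$$g(d) = \frac{e^{-2}}{2\pi\sigma^2}\, e^{-d^2/2\sigma^2}
  \quad (d \le 1.5), \qquad g(d) = 0 \quad (d > 1.5),$$

with $\sigma = 0.5$, and $m_i = \phi(a_s g(d_{is}) + a_w g(d_{iw}))$
where the source activations $a_s, a_w$ mirror the two seasonal
feedback inputs.  The prefactor is read literally as the planar
Gaussian normaliser $e^{-2}/(2\pi\sigma^2)$; a one-dimensional reading
$e^{-2}/(\sigma\sqrt{2\pi})$ is selectable via `falloff_normalizer`
since the printed form is ambiguous about a lost square root.  The
cutoff comparison is at-or-below 1.5.  Because $\phi(0) = 0$ exactly
and $g$ is exactly 0 beyond the cutoff, two invariants hold bit-for-bit
and are tested as such: connections whose target is out of range of
every *active* source never change, and an agent that never eats ends a
diffusion lifetime with exactly its initial weights.

**Update pairing.**  The seasonal feedback about item $t$ arrives one
step later, together with item $t+1$.  Which activations should the
Hebbian product use when that signal arrives?  Pairing it with the
*current* step's activations correlates the outcome of one item with
the encoding of an unrelated next item; consecutive presentations
within a day are drawn without replacement and are therefore slightly
anti-correlated, so the only association signal left is a weak
second-order one, and in our experiments hand-built "ready-to-learn"
diffusion networks then plateau near chance.  Pairing the arriving
signal with the activations of the presentation that *caused* it — an
eligibility-style rule, with the eligibility cleared at season
boundaries — gives item-wise credit assignment, and the same hand-built
networks learn both seasonal rules within a lifetime (testing fitness
0.875–1.0), reproducing the within-lifetime learning the model system
is designed to show.  `plasticity_config(update_pairing = )` exposes
both; `"eligibility"` is the default.  Under either pairing the
modulatory signal itself is computed from the current step (the
wire-borne rule needs the current forward pass, which is what carries
the feedback inputs to modulatory nodes).

The learning step follows each forward pass; weights are not clamped
by default (at $\eta = 0.002$ a connection can drift at most ~0.5 over
a 240-step lifetime), though a symmetric clamp is available.

## Evolution

Networks evolve under PNSGA — NSGA-II non-dominated sorting with
crowding in which each objective enters the sort with a fixed
probability, sampled once per generation.  Objectives: mean training
fitness over 4 lifetimes in fresh environments (shared by the whole
population and redrawn every generation, so seasonal rules cannot be
hard-coded), behavioral diversity (mean normalised Hamming distance
between concatenated eat/not-eat vectors), and, in the `PCC`/`PCC_D`
treatments only, a minimised connection count included with
probability 0.75.  Selection is elitist (μ+λ): parents and offspring
are evaluated together on the generation's environments and the best
`population_size` survive; offspring arise by binary tournament on
(rank, crowding) followed by mutation only.  Mutation applies one
add-connection and one remove-connection attempt (p = 0.20 each, add
uniform over absent legal forward pairs), per-connection endpoint
reassignment (p = 0.15, one rejection-resample then no-op) and
polynomial weight mutation (p = 2/n), and per-node polynomial mutation
of bias and `modul` (p = 0.10 each).  The polynomial-mutation
distribution index is 15, the customary default, as no value is
prescribed; add/remove are interpreted as per-genome attempts (flagged
in the configuration), and the connection cost is the plain connection
count.  Objective inclusion is sampled per generation rather than per
comparison — the simplest semantics consistent with an objective
"factoring into selection" a given fraction of the time, and the one
that keeps runs reproducible from a single seed.

## Seasonal-association metrics

At the end of each of the six seasons of a training phase, learning is
switched off, both feedback inputs are silenced, and all eight items
are probed against each season's rule on the season-appropriate
output.  An association is *Known* if all eight classifications are
correct; a season end where both are Known is *Perfect*; an
association Known at one season end is *Retained* or *Forgotten* at
the next.  *Retained Percent* is 100 × Retained / Known, where Known
counts the associations at risk of a transition (so Retained +
Forgotten = Known); 0/0 is defined as 0.  A learner can be Perfect at
no more than 5 of 6 season ends (it has seen only one season at the
first probe), giving the 400 ceiling over 80 environments; an agent
that only ever knows the current season is Perfect exactly at the 6
season ends of identical-rule environments, which arise with
probability 1/6.

## ARK: from activation records to functional modules

The testing phase (learned weights, learning off, same environment)
yields an *activation record*: every node's activation at each of the
240 presentations.  For a node with $p$ incoming connections, ARK
recomputes its activation at every recorded step from the *recorded*
activations of its in-neighbours for each of the $2^p$ kept-subsets
(knockouts do not propagate; each node's table is independent of
traversal order) and scores each subset by the standard error of
regression against the recorded series,
$\mathrm{SER} = \sqrt{\sum_i (y_i - \hat y_i)^2 / n}$.  The root
reading is adopted: the conventional "standard error of regression" is
a root quantity, and thresholds on the order of 0.7 are only sensible
for activations in (−1, 1) under the root; the denominator is $n$ as
printed rather than a regression-style $n-2$, and a flag selects the
non-root reading.  Tables are sorted by SER, ties broken by larger
subset; selection takes the smallest subset at or below the error
threshold (ties: lower SER, then lower mask).  Extraction walks
breadth-first from a season's output, keeping each visited node's
selected connections and enqueueing their sources in ascending id
order; the kept union is that season's functional subnetwork.  The
threshold search starts at the largest all-kept recomputation error
across nodes plus 10⁻¹², rises in steps of 0.01, and keeps the last
CFN whose testing fitness has not dropped below the original's — so a
CFN never loses fitness by construction.  Connections in both seasonal
subnetworks form the *common* module.  In-degrees above 20 are refused
(the enumeration is exponential).  Nodes whose recorded activation
variance is below 10⁻⁹ (strict) are flagged as bias nodes.  A
one-connection knockout validation removes one random connection per
module label and re-runs the testing phase: in hand-built dual-module
networks, removing a winter connection leaves summer fitness exactly
unchanged and strictly lowers winter fitness, and symmetrically.

## Functional modularity

`q_score()` computes Newman modularity on the undirected, unweighted
projection of a network (the metric is defined for undirected graphs;
learned weights and edge directions are deliberately discarded).
Partition search uses greedy agglomerative merging
(`igraph::cluster_fast_greedy`), which is deterministic; edgeless
graphs score 0 by convention.  The Q of a CFN is its *functional
modularity*.

## Problem sizes and numerical choices

The full-scale study profile (population 400, 20 000 generations, 50
runs, 80 post-evolution environments) ships as the default
`evolution_config()` but is a configuration choice, not something the
test suite runs.  The packaged test suite exercises the directional
comparison at a desk profile — 5 paired runs per treatment, population
100, 300 generations, 8 post-evolution analysis environments with ARK
on 4 of them — chosen as the largest profile that keeps a full test
run interactive on a single core; the methods themselves are identical
at every scale.  Seeds flow from a single master seed through
`derive_seed()` (a 32-bit multiplicative scheme), so any individual
run or analysis environment can be replayed in isolation.

Known limitations: at the desk profile evolution has typically not yet
discovered weight-based learners — champions tend to be reactive
policies that read the feedback inputs directly, whose training fitness
matches that of early learners — so desk-scale treatment comparisons on
the retention metrics are noisy and may be statistically
indistinguishable; the within-lifetime learning mechanism itself is
therefore validated directly on hand-constructed networks rather than
through evolved ones.  The diffusion model is steady-state (no temporal
diffusion dynamics, by construction).  ARK's frozen-record semantics
mean a kept subset is judged by local reconstruction error, not by
re-running the network — the fitness guarantee comes from the threshold
search, which does re-run it — and nodes with more than 20 incoming
connections are refused rather than enumerated.
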