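---
title: "Inferring dominance hierarchies and their certainty from agonistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dominance hierarchies and their certainty from agonistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dominet)
```

## The problem

Behavioural ecologists summarize agonistic (aggression/submission) data as a
win/loss matrix: cell $(i, j)$ counts the decided encounters individual $i$
won against $j$. Classical ranking methods (I&SI, David's Score, Elo) assume
a linear hierarchy and struggle when the matrix is sparse — many dyads are
never observed to interact, either through sampling limitations or because
animals genuinely avoid each other. `dominet` treats the matrix as a
directed network and exploits the *flow* of dominance through indirect
pathways: if A beats E and E beats D, the path A→E→D carries information
about the unobserved A–D relationship. This yields three things a linear
rank alone does not give:

* a dominance probability (DP) for every dyad, including non-interacting
  ones;
* a *dominance certainty* (DC) measure at the dyadic, individual and group
  levels — how decided relationships are, which can matter biologically as
  much as rank itself;
* nonlinear structure: rank *tiers* of individuals whose mutual
  relationships stay ambiguous.

## From counts to dominance probabilities

**Network.** Each strictly positive cell becomes a directed, weighted edge;
both directions of a dyad may coexist. Isolated individuals stay in the
network.

**Transitivity.** Every dyad is binarized by majority count (ties —
including 0–0 — are undecided). Among node triples whose three dyads are
all decided, a triple is *transitive* if one member dominates the other
two and one is dominated by both, and *cyclic* otherwise. The transitivity
index is

$$t = \frac{\#\text{transitive}}{\#\text{transitive} + \#\text{cyclic}}.$$

When no triple is fully decided, $t$ is undefined and the package uses a
configurable default of 1 (`defaultTransitivity`). The rationale: absence
of any closed triangle means no intransitivity was ever observed, and a
default of 0 or 0.5 would throw away all indirect information in sparse
chain-like networks — exactly the data the method is meant to help with.
The default is recorded in every summary so it is never silently applied.

**Path weighting.** Indirect information is only trustworthy to the extent
that the network's higher-order structure is transitive. A simple directed
path of length $\ell$ (edges) is weighted

$$w(t, \ell) = \beta^{\ell - 1}, \qquad \beta = \max(0,\, 2t - 1),$$

so a fully transitive network ($t = 1$) trusts paths completely, a network
whose triangle directions are at chance ($t \le 0.5$) contributes nothing
through paths, and longer paths are discounted geometrically. The specific
affine-geometric form is this package's calibration choice; the defining
constraints are that the weight increases with $t$, vanishes at chance
transitivity, and decays with length.

**Evidence.** For every ordered pair $(i, j)$,

$$e_{ij} = c_{ij} + \sum_{p\,:\,i \to \cdots \to j,\ 2 \le \ell(p) \le L}
w(t, \ell(p)) \prod_{(u,v) \in p} \frac{c_{uv}}{c_{uv} + c_{vu}},$$

where the product is the *directional consistency* of the traversed edges.
Each path can therefore contribute at most one imputed ("fractional") win:
a long noisy chain can never outweigh direct observation, and indirect
evidence deliberately does not grow with raw observation effort the way
direct counts do. Paths in the two directions of a dyad are imputed
independently; no netting occurs before the probability step. Only simple
paths (no repeated individuals) are enumerated — revisiting an individual
adds no independent information and breaks termination.

The default maximum path length is $L = 2$, configurable up to 6 with a
warning: enumeration is exhaustive and the path count grows
combinatorially in dense networks, while paths beyond length 2–3 are
heavily discounted anyway unless $t \approx 1$.

**Dominance probability.** With a symmetric smoothing prior of $s$
pseudo-wins per direction (default $s = 0.5$, a Jeffreys-style half win),

$$\mathrm{DP}_{ij} = \frac{e_{ij} + s}{e_{ij} + e_{ji} + 2s}.$$

This guarantees $\mathrm{DP}_{ij} + \mathrm{DP}_{ji} = 1$ and places dyads
with no evidence in either direction — e.g. pairs in disconnected
components — exactly at $0.5$, the fully ambiguous midpoint of the DP
colour scale.

## Rank order, tiers, and the rank tree

The rank order is the permutation maximizing the upper-triangle sum
$\sum_{a<b} \mathrm{DP}_{o_a o_b}$. For groups up to `exactMaxN = 8` the
package scans all $n!$ permutations; among exact ties the
lexicographically smallest id sequence is returned, so results are fully
reproducible. Larger groups use seeded simulated annealing: adjacent
transpositions (75% of proposals) and random pair swaps under a geometric
cooling schedule (factor 0.97, 150 temperature steps of $n$ moves, initial
temperature set to the standard deviation of sampled single-move deltas),
each restart finished with deterministic hill-climbing passes (adjacent
swaps, pair swaps, single-element reinsertion) to convergence. The first
restart starts from the descending row-sum order; the remaining restarts
(default 50 in total) start from random permutations. The multistart
design exists because the upper-triangle objective has genuine local
optima whose basins can capture *every* run started from one fixed order;
random restarts make the per-restart searches independent, and the
best-of-ensemble with lexicographic tie-breaking keeps the output
deterministic for a given seed.

Nonlinearity is expressed two ways:

* **Tiers** scan the best order top-down and merge adjacent individuals
  whose DP (higher over lower) falls below a threshold (default 0.70, the
  conventional ambiguity cutoff for "indistinguishable" neighbouring
  ranks). Tiers are contiguous runs along the diagonal of the reordered
  matrix, which keeps their semantics well defined.
* The **rank tree** is average-linkage clustering of the distances
  $d_{ij} = |2\,\mathrm{DP}_{ij} - 1|$ (0 = fully ambiguous, 1 = fully
  decided); cutting it at height $2(\tau - 0.5)$ corresponds to the tier
  threshold $\tau$ and is provided for visualization. The distance form is
  this package's documented choice of rank distance.

## Dominance certainty

$$\mathrm{DC}_{ij} = \max(\mathrm{DP}_{ij},\, \mathrm{DP}_{ji}) \in [0.5, 1],$$

symmetric by construction; individual DC is the mean over all of an
individual's dyads (non-interacting partners included — their certainty is
exactly what the indirect machinery estimates), and group DC is the mean
of individual DCs, which is algebraically identical to the mean over
unordered dyads.

**Inferential vs biological uncertainty.** A DC near 0.5 can mean "not
enough data" or "genuinely unsettled relationship". The
`certaintyDiagnostics()` summary classifies dyads as interacting or
non-interacting and reports the distribution of indirect-path counts per
class, plus a descriptive flag: when transitivity is high (default cutoff
$t \ge 0.9$) and non-interacting dyads still have abundant paths (default:
median $\ge 1$), their ambiguity is *likely biological*; when transitivity
is low or paths are scarce, *likely inferential*. The cutoffs are
configurable and always reported; no hypothesis test is implied.

## The simulator

`simulateGroup(n, a, lambda, z, seed)` draws agonistic data from a known
latent linear hierarchy: latent ranks $1..n$ are assigned at random; each
unordered dyad is a structural zero with probability $z$, otherwise it
draws a Poisson($\lambda$) number of encounters, each won by the
higher-ranked member with probability $1/(1 + e^{-a\Delta})$ where
$\Delta$ is the absolute rank difference. This is the minimal steepness
model: $a = 0$ gives fair coins, large $a$ a despotic hierarchy in which
the census is fully transitive. Structural zeros are independent across
dyads — the simplest stand-in for avoidance or demographic barriers,
without kin or spatial structure.

The reference study conditions used throughout the validation are
$n = 15$, $a = 2$, $\lambda = 10$, $z = 0.3$, ten replicate seeds: a
moderately steep hierarchy (adjacent ranks decided at $p \approx 0.88$
per encounter), realistic per-dyad observation effort for focal-sampled
primate groups, and substantial sparsity. These sizes keep the full
validation (including the 100-instance annealing-vs-exhaustive check) to
well under a minute each while being large enough for annealing rather
than exact search to be exercised.

What the simulator does **not** emulate: kin-structured alliances and
matrilineal rank inheritance, temporal rank dynamics, observation biases
correlated with rank, and winner/loser effects. Passing recovery tests on
these synthetic groups shows the inference machinery is sound, not that
any particular field dataset meets the model's assumptions.

Two deterministic generators complete the test bed: `linearChain()` (only
adjacent dyads interact; everything else must come from paths) and
`cycleNetwork()` (pure circularity; with $t$ forced to 0, non-adjacent
dyads stay exactly at DP 0.5). `indirectPathwaysFixture()` encodes the two
canonical motifs — parallel consistent pathways (A over D, never observed
directly) and contradictory pathways (I over F via one short path, F over
I via a longer chain) — in one 9-individual matrix; two parallel
consistent pathways are used, a fixture choice, since any number of
same-direction paths gives the same qualitative contrast.

## Numerical and design notes

* Ties are broken lexicographically by id everywhere (exact search,
  ensemble best, starting order), so identical inputs give identical
  outputs.
* Validation failures raise typed conditions (`dominet_*_error`), which
  the CLI maps to nonzero exit codes with the condition class named in
  the message.
* The dyadic identity $\mathrm{DP}_{ij} + \mathrm{DP}_{ji} = 1$, the
  neutrality of evidence-free dyads, and the group/individual/dyadic DC
  aggregation identity are exact (not approximate) properties of the
  formulas and are asserted to $10^{-12}$ in the tests.
* Adding one direct win for $i$ over $j$ cannot decrease
  $\mathrm{DP}_{ij}$: indirect $i \leftrightarrow j$ paths never traverse
  the $(i,j)$ edges, so the dyad's own evidence moves only in $i$'s
  favour. A transitivity shift elsewhere in the network rescales both
  directions' indirect evidence by the same length-dependent factor; the
  property held in $10^3$ randomized trials with transitivity recomputed.
* Because each path's contribution is capped at one fractional win,
  multiplying all counts by $k$ (more observation effort, same directions)
  increases DC through the direct route but leaves imputed evidence
  unchanged; where indirect evidence dominates a balanced dyad, its DC can
  move toward the direct signal. This is intentional: imputed wins measure
  pathway consistency, not observation volume.

## Known limitations

* The certainty U-shape across ranks (extreme ranks more certain than
  middle ones) is reproduced in the mean rank profile of the reference
  simulations, but the per-replicate quartile contrast is small relative
  to its sampling noise at $n = 15$; the `ushape_fraction` quantity
  computed by `scripts/acceptance.R` is accordingly seed-sensitive.
* Exhaustive path enumeration limits practical $L$; the default $L = 2$
  is also where the imputation is least model-dependent.
* DP values are point probabilities; no posterior intervals are provided.
* Parity with other implementations of pathway-based ranking is not
  claimed; the weighting calibration above is this package's own.
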