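---
title: "Game-theoretic coarse-grained sampling of RNA 3D structures: models and methods"
author: "rnagame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Game-theoretic coarse-grained sampling of RNA 3D structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnagame)
```

## The model

RNA folding is hierarchical: the secondary structure (helices, loops,
junctions) forms first and largely persists in the 3D fold, so the hard
part of tertiary prediction is the *spatial arrangement* of the
secondary-structure elements (SSEs). `rnagame` samples that arrangement
at a deliberately coarse scale. Each SSE becomes one or a few *players*
on a face-centred cubic (FCC) lattice, and sampling proceeds as a
repeated game in which each player egotistically maximizes its own
knowledge-based score rather than a global energy. Stable configurations
of such a game — approximations of Nash equilibria — are read as
candidate coarse 3D folds, useful as starting points for higher
resolution modelling.

### From dot-bracket to player graph

`parseDotBracket()` builds a nested set of base pairs;
`decomposeSSEs()` finds maximal helices and the loop regions they
enclose (terminal loops, bulges and internal loops, three- and four-way
junctions). `buildPlayers()` then applies the coarse-graining rules:

* a helix of $b$ base pairs becomes $\lceil b/5 \rceil$ players (at most
  five base pairs each, so long helices retain some flexibility);
* terminal loops, bulges and two-way junctions become one player each;
* a three-way junction becomes **two** players: a STACK player standing
  for the first base pair of the two coaxially stacked helices, and a
  BRANCH player standing for the junction nucleotides;
* a four-way junction is modelled as two three-way junctions joined by a
  LINKER player (five players in total).

Which two helices of a three-way junction stack coaxially is an input
(`stackingHint`); when absent, the two helices whose connecting strand
is shortest are stacked. This default is a deterministic heuristic, not
a prediction of coaxial stacking: real stacking assignments should come
from the user when known.

`buildGraph()` connects players along the covalent chain into a tree.
Edges carry a lattice length: 1 step between the STACK and BRANCH
players of one junction (players of the same junction sit one lattice
unit apart), 2 steps for every other adjacency, including between
consecutive players of one long helix — a five-base-pair rise of
A-form RNA (11–14 Å) is much closer to two lattice steps (11.2 Å) than
to one. Pseudoknots are rejected (the tree model assumes nested
structure), as are top-level unpaired nucleotides and multiple top-level
helices (the evaluation regime assumes paired 5'–3' ends).

The playing order is a depth-first preorder. The root is the junction of
largest degree nearest the 5' end (its STACK player for three- and
four-way junctions); molecules whose only "junctions" are terminal
loops are rooted at the 5'-most helix player instead, so a hairpin
orders as (helix, loop) and a chain keeps its natural order. At a
three-way junction the subtree through the unstacked helix is visited
first.

### The lattice

The "3D triangular" lattice of coordination number 12 is realized as
the even-coordinate-sum sublattice of $\mathbb{Z}^3$, whose nearest
neighbour vectors are the 12 signed permutations of $(1,1,0)$. All
geometry is exact integer arithmetic: angles between directions come
from integer dot products (only 0°, 60°, 90°, 120°, 180° occur), and
segment–segment intersection is decided exactly with 64-bit integer
cross products. One lattice step is calibrated to 5.6 Å — the dominant
mode of observed adjacent-player distances for same-junction players,
with the second mode at 11.2 Å (two steps) for players of different
SSEs — so `toCartesian()` simply scales integer coordinates by
$5.6/\sqrt{2}$.

A conformation is valid when all players occupy distinct sites, every
tree edge is a straight lattice segment of its stated length, no
length-2 edge passes through an occupied site (length-2 edges occupy
their midpoint, which is itself a lattice site), and no two edges
intersect. A useful property of this lattice, which the test suite
verifies against a floating-point oracle, is that two straight
nearest-neighbour segments can only meet at lattice sites, so occupancy
checks and exact segment tests agree.

### Strategy sets

A player's action orients its outgoing tree edge, i.e. places its child
(for the three-way STACK player, the first action places the BRANCH
player). Players with several children hold one 12-armed bandit per
outgoing edge. The admissible directions depend on the player:

* helix players keep their incoming direction or bend by at most 60°
  (5 of the 12 directions); small two-way junctions (one unpaired side
  shorter than two nucleotides) behave the same;
* a *frozen* helix player may only continue straight. Freezing applies
  to helices of more than five base pairs (the multi-player helices that
  could otherwise kink) when the game configuration requests it;
* all other junction players, and the root, may use all 12 directions.

Directions whose application would collide or cross an edge are removed
each turn; a player whose legal set is empty skips its turn without any
state update. Applying an action rigidly translates the whole subtree
below the child, preserving its internal geometry — the alternative
(re-randomizing the subtree) would make one action a global rather than
local decision.

## Knowledge-based scoring

Four pairwise functional forms score the Cartesian distance $d$ between
two players, with parameters per unordered SSE-type pair:

* Lennard-Jones: $-A\left((B/d)^{12} - 2 (B/d)^6\right)$, one mode of
  height $A$ at the preferred distance $B$;
* modified Lennard-Jones: the repulsive branch clamped to zero,
  $\max(\mathrm{LJ}, 0)$ — zero below $B\,2^{-1/6}$;
* Gaussian mixture: $\sum_k A_k\,\mathcal{N}(d;\mu_k,\sigma_k)$, several
  modes;
* inverse square: $1/d^2$.

A player's score is the sum of pair scores to all **non-adjacent**
players (edge-connected neighbours sit at fixed lattice distances, and
the potentials are fitted from non-adjacent distance statistics, so
adjacent pairs carry no information); the total score is the sum over
players, and $\mathrm{Energy} = -\mathrm{TotalScore}$ for
energy-vs-RMSD diagnostics.

`fitPairParams()` estimates parameters from observed distances. For the
LJ forms, $B$ is the mode of a kernel density estimate computed with
twice the reference bandwidth: distance distributions are smooth and
only the mode location matters, so oversmoothing trades a little bias
for much lower variance (raw-bandwidth mode estimates on $10^4$ samples
fluctuate beyond 2%; the doubled bandwidth stays within it while still
resolving modes several standard deviations apart). The Gaussian form is
a finite mixture fitted by EM with the component count (1–5) selected by
BIC via `mclust`; the mixture weights become the amplitudes. Every
fitted entry is normalized so the supremum of the score over the
observed distance range is 1. The inverse-square form needs a special
rule — its supremum near zero is unbounded — so it is normalized by its
value at the smallest observed distance; scores beyond that range are
clamped when converted to rewards.

When a helix is frozen it cannot bend, so its own pair sums would mostly
reflect rigid geometry; instead its score borrows from its surroundings:
the scores of its nearest junction players (walking through helix
players only), each divided by its hop distance in the player graph,
averaged over those neighbours.

## The game

Two regret-minimizing bandit algorithms drive the players:

* **UCB1**: pick the legal arm maximizing
  $\bar r_a + c\sqrt{2\ln t / n_a}$ (default $c = 1$); unpulled legal
  arms are taken first, in canonical direction order.
* **EXP3**: sample from
  $p_a = (1-\gamma)\,w_a/\sum w + \gamma/K$ restricted to the legal set
  (default $\gamma = 0.1$), then update
  $w_a \leftarrow w_a \exp\!\left(\gamma\, r/(p_a K)\right)$.

Rewards are the player's own score divided by its number of non-adjacent
partners (each normalized pair term has supremum 1, so this is the
natural $[0,1]$ scale), clamped to $[0,1]$.

Three turn schedules are supported. **AA**: every player-edge selects an
action against the start-of-turn conformation; actions are applied in
DFS order with legality re-checked at application (a selection that
became illegal is skipped); then all acting bandits update with the
post-turn rewards. **OA**: one player (round-robin in DFS order) plays;
then *every* player-edge updates — non-acting edges re-attribute the new
reward to their most recently selected action, which keeps UCB means and
EXP3 importance weights well defined. **OO**: one player plays and only
its own bandits update. In OA/OO the per-run turn budget is the
configured $k$ divided by the number of players. The default budget is
$k = 4000$.

`defaultGameplay()` encodes the molecule-feature rule: no three-way
junction → OA / UCB / modified LJ / frozen helices; otherwise AA / EXP3,
unfrozen, with plain LJ when the ratio of helix players to junction
players exceeds 1.5 and modified LJ otherwise. Intuitively, UCB performs
a local optimization appropriate for smooth, simple landscapes, while
EXP3's Boltzmann-like sampling tolerates the rugged score changes that
three-way junctions induce; helix-dominated molecules need the
repulsive part to prevent unphysical packing, junction-dominated ones
sample better without it.

A *sample* is the final conformation of one independent seeded game
(seeds $s, s+1, \dots$ for $n$ samples); independent runs maximize
diversity and are embarrassingly parallel. Everything downstream of the
seed — embedding, EXP3 draws, tie-breaks — is deterministic, so a
(structure, parameters, configuration, seed) tuple reproduces a sample
set byte for byte.

### Regret

For player $i$ after $T$ turns,
$\mathrm{Regret}_i(T) = -\sum_{t \le T} s_i(t) + \max_{p \in
\mathcal{A}_i} \sum_{t \le T} s'_{i,p}(t)$, where the counterfactual
$s'_{i,p}(t)$ is player $i$'s score at the recorded turn-$t$
conformation with its child re-placed by the fixed direction $p$ (the
subtree translating rigidly; legality is not imposed on
counterfactuals). $\mathcal{A}_i$ is the player's strategy set at its
initial orientation, so a frozen helix player has a single strategy and
identically zero regret. A decaying average regret indicates the play
approaching the best fixed response in hindsight.

One caveat the test suite documents explicitly: the *extreme* per-turn
regret increment does not die out under EXP3, because a constant
$\gamma$ keeps at least $\gamma/K$ probability on every arm forever —
roughly one turn in ten is an exploration move in any window, and the
window maximum of the increment therefore saturates at the largest
attainable instantaneous score gap early and late alike. The
corresponding stationarity check in `test-acceptance.R` is kept at its
stated threshold and is expected to fail under these study conditions;
the regret *curve* (cumulative, per strategy) is the meaningful
diagnostic.

## The synthetic reference ensemble

The potentials are meant to be fitted from a reference set of solved
structures. To keep the whole pipeline testable without downloads,
`makeReferenceEnsemble()` manufactures coordinate sets for a given
player graph in which adjacent players sit exactly at their lattice edge
distances while non-adjacent inter-player distances follow user-stated
laws (Gaussian or two-component Gaussian per type pair). Each structure
is built by sequential placement along the DFS order followed by a joint
BFGS refinement of all edge directions against distance targets drawn
from the laws; because the hard edge constraints bias realized distances
on branched graphs, the generator then *calibrates*: it measures the
per-pair-class residual bias, shifts the target means accordingly, and
regenerates, stopping when every class mean is within `tol` of its law
mean.

What this emulates is the one statistical property the fitting step
consumes — the non-adjacent distance distributions by type pair. What it
does **not** emulate: real RNA geometry (sequence effects, junction
anisotropy, excluded volume at atomic scale), realistic correlations
between pairs, or lattice discretization of the native coordinates.
Passing fitting-recovery tests on these ensembles therefore shows the
estimators work, not that the potentials are biophysically calibrated.
On chain topologies the default 5% class-mean tolerance is met easily
(within ~1%); on branched topologies the feasible means are constrained
by the fixed edge geometry and a tolerance of ~10–15% is realistic —
`tol` is a feasibility statement about geometry, not a fitting accuracy.

## Evaluation

Native structures are coarse-grained by `coarseGrainNative()`: each
player's coordinate is the unweighted mean of the heavy (non-hydrogen)
atoms of its nucleotides, with the three-way STACK player using the
first base pair of the two stacked helices and the BRANCH player all
junction atoms. `rmsd()` computes
$\sqrt{\tfrac1p \sum_i \lVert m_i - n_i \rVert^2}$ after an optimal
least-squares superposition (Kabsch via SVD, determinant forced to $+1$
so reflections are excluded; a flag disables superposition for the
literal formula). `summarizeSamples()` reports the min/max RMSD, the
count below a threshold, and (Energy, RMSD) pairs.

## Numerical choices and problem sizes

* All indices are 1-based; lattice coordinates are integers; geometric
  predicates are exact.
* `randomEmbedding()` places players in DFS order uniformly over legal
  directions with restart-on-dead-end (default 1000 restarts before an
  error); embeddings are seeded and reproducible.
* Ties in UCB and in direction enumeration break by the canonical
  lexicographic direction order; ties in stacking by 5' order.
* EXP3 weights are renormalized when they exceed 1e100 (only ratios
  matter).
* The test suite and the acceptance script run on toy fixtures (2–12
  players), with $10^4$-sample fitting problems, $10^4$-pull bandit
  checks, $10^4$ random embeddings for the self-avoidance sweep, 50-game
  sample sets at 1000 turns, and 20 games of 4000 turns for the regret
  diagnostics — sizes chosen so the full pipeline, not a reduced stub,
  is exercised on every run.

## Known limitations

* Pseudoknots, dangling ends, and junctions of degree greater than four
  are rejected rather than approximated.
* The coaxial-stacking default (shortest connecting strand) is a
  heuristic; supply `stackingHint` when the stacking is known.
* Scores are relative, sup-normalized quantities: they rank
  conformations within one parameter set and are not transferable
  energies; the package's own diagnostics show they do not form a sharp
  funnel to low RMSD, so they should not be used to sort samples.
* The sampler explores conformations of the *given* secondary
  structure; it does not predict secondary structure, reconstruct
  atoms, or refine off-lattice.
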