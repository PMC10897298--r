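---
title: "Greedy modularity with disassembly exploration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy modularity with disassembly exploration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgmod)
```

## The problem

Community detection asks for a partition of a network's nodes into groups
that are densely connected internally and sparsely connected to the rest.
In systems biology this is the standard route from a protein--protein
interaction or metabolic network to candidate functional modules. The
quality function used throughout this package is Newman modularity

$$Q(S) = \sum_{c \in S}\left(\frac{l_c}{L} - \left(\frac{k_c}{2L}\right)^2\right),$$

where $l_c$ is the number of edges inside community $c$, $k_c$ the summed
degree of its members and $L$ the number of edges. $Q$ compares the
internal edge fraction against a degree-preserving null model; it is 0 for
the all-in-one partition and bounded by $[-1/2, 1)$. Maximizing $Q$ is
NP-hard, so practical methods are heuristics.

The classic agglomerative heuristic (Clauset--Newman--Moore, "CNM") starts
from singleton communities and repeatedly merges the pair of communities
with the largest modularity gain

$$\Delta Q = 2\,(e_{ij} - a_i a_j),$$

with $e_{ij}$ the fraction of edge endpoints joining communities $i$ and
$j$ and $a_i = k_{c(i)}/(2L)$, stopping when no merge gains. Only this
fractional normalization makes $\Delta Q$ the exact difference
$Q_{\text{after}} - Q_{\text{before}}$, and the package enforces that
identity by test (to $10^{-12}$ per merge, $10^{-9}$ cumulatively). Pure
CNM is deterministic here: ties in $\Delta Q$ are broken by the smallest
community-id pair. Because it never undoes a merge, CNM routinely stops in
local optima.

## Exploration by disassembly

The package's search, `run_dgm()`, interleaves that greedy exploitation
with stochastic *disassembly* moves that break structure apart so that
exploitation can rebuild it differently:

* **node disassembly** removes one node from its community: the node
  becomes a singleton and the remainder of the community is split into its
  connected components;
* **community disassembly** dissolves a whole community into singletons.

Targets are chosen by quality criteria. For nodes: uniformly at random; a
*weak* node (internal degree $\le$ external degree, internal degree at
least 2 so the node genuinely sat inside the community); the node of
lowest *embeddedness* $k_v^C/k_v$; or a node participating in no internal
triangle (only in communities with more than four members). For
communities: uniformly at random; the *weak* community (smallest
internal-minus-external edge balance $l_c - m_{out}$); lowest internal
edge density $m_s/\binom{n_s}{2}$; lowest triad participation ratio (the
fraction of members in at least one internal triangle); or highest
conductance $m_{out}/(2 m_c + m_{out})$. All argmin/argmax ties are broken
uniformly at random from the seeded stream, which preserves exploration
diversity while keeping runs exactly reproducible per seed.

Each iteration draws $u \sim U[0,1)$: with probability `p_comm` (default
0.05) a community move fires, with probability `p_node` (default 0.05) a
node move, otherwise the best positive merge is applied. The iteration
budget is $T = \lceil p\,n \rfloor$ with multiplier `iter_multiplier`
(default 30); the best $(Q, \text{partition})$ snapshot over all
iterations and restarts is the result. Restarts are plain independent
reseeds (`seed + r - 1` for restart $r$).

### Exploration starts at the first local optimum

Exploration draws before the search first reaches a local optimum are
no-ops. This makes the plain greedy trajectory a prefix of every run, so
the returned best can never fall below the greedy baseline — a property
the test suite asserts per seed — and it matches the view of exploration
as a *correction* step for a search that has stalled. A side effect is
that a configuration with `p_node + p_comm = 1` (no exploitation) never
leaves the singleton state: with nothing built, nothing can be
disassembled.

### Escaping local optima: the two-scale schedule

What should happen when exploitation is drawn but no merge gains? Doing
nothing wastes the iteration; always dissolving one community turns out to
be almost useless, which we established by mapping the search landscape on
the karate club network (see below). The committed design is an *escape
schedule* at two scales, in the spirit of iterated local search:

* by default an escape applies **two** node-disassembly moves (configured
  node strategy, falling back to a random node when the strategy has no
  candidate) before exploitation resumes;
* every fourth consecutive escape without an improvement of the best
  modularity applies one **community** disassembly (configured community
  strategy) plus one node move;
* the consecutive-escape counter resets whenever the best modularity
  improves.

The rationale is structural. On the karate club network the
kick-and-repair transition graph (disassemble something, then let
deterministic greedy repair run to convergence) has an absorbing local
optimum: no *single* disassembly followed by full repair escapes it, so a
stuck search that always applies one kick and waits for repair revisits
the same partition indefinitely. Escaping that basin needs a
community-scale kick, while converting the next plateau into the global
optimum needs *pairs* of node-scale kicks interleaved with partial
repair — and an intervening community kick destroys exactly that pattern.
Kicking at both scales on a schedule resolves the conflict: the test
suite verifies that the configured search then recovers the karate
optimum ($Q = 0.4198$, four communities) within its 50-restart budget and
attains the exhaustive-enumeration optimum on small random graphs.

## Choices a user can tune

| parameter | default | meaning |
|---|---|---|
| `p_node`, `p_comm` | 0.05 each | per-iteration exploration probabilities |
| `iter_multiplier` | 30 | budget $T = p\,n$ iterations |
| `n_restarts` | 1 | independent reseeds, best kept |
| `node_strategy` | `random` | node-disassembly criterion |
| `community_strategy` | `weak` | community-disassembly criterion |
| `exploit_to_convergence` | `FALSE` | greedy to convergence per exploitation iteration instead of one merge |

One merge per exploitation iteration is the default because it matches the
gradual climb-and-drop shape of the per-iteration modularity trace; the
convergence variant is offered as a flag and did not improve results in
our experiments.

## Numerical conventions

* Modularity is always unweighted; weights found in input files are
  ignored with a warning. The bundled karate faction labels score
  $Q = 0.3582$ and mean internal density $0.2463$ under this convention.
* `delta_q` is exact: merging and recomputing from tallies agree to
  $10^{-12}$; all incremental state is cross-checked against from-scratch
  recounts in the tests at $10^{-9}$.
* NMI uses $2 I(U;V)/(H(U) + H(V))$ from the co-membership contingency
  table (any log base; the ratio is base-invariant). The $0/0$ cases are
  resolved by convention: two single-community partitions are identical
  (NMI 1), one trivial against a non-trivial partition scores 0.
* Mean internal density averages per-community densities *unweighted* and
  skips singleton communities, whose density is undefined.
* Degenerate metric inputs (isolated nodes for embeddedness, singleton
  communities for density, zero-degree communities for conductance) raise
  errors rather than returning sentinel values; strategy selectors simply
  exclude such communities.

## The planted-partition generator

`generate_planted()` emulates LFR-style benchmarks: community sizes from a
truncated power law (exponent `beta`, default 1.5), degrees from a
truncated power law (exponent `gamma`, default 3; lower cutoff tuned to
the target mean degree, upper cutoff about $n/10$), and each node's edges
split internal/external by the mixing parameter $\mu$. Internal edges are
realized per community with a degree-sequence model; external stubs are
paired across communities with rejection of self-loops, duplicates and
same-community pairs, and bounded retries. The empirical mixing fraction
is reported and stays within 0.05 of the requested $\mu$ at benchmark
sizes; at $\mu = 0$ it is exactly 0. Defaults (`n = 250`, mean degree 10,
community sizes roughly 27--67) were chosen once as a realistic benchmark
scale for the sweep experiments.

What the generator does *not* reproduce: degree--community-size
correlations of full LFR, overlapping communities, weighted edges, or
bit-compatibility with any published LFR implementation. Passing tests on
these benchmarks therefore demonstrate behaviour under clean power-law
planted structure, not performance on any particular real data set.

The `ring_of_cliques()` fixture ($k$ cliques of size $s$ joined in a ring
by single bridges) provides an analytically known optimum for oracle
tests.

## Problem sizes used by the test suite

The suite checks the headline karate numbers (ground truth 0.3582 /
0.2463; greedy baseline about 0.3807 with 3 communities, asserted as the
range [0.38, 0.39] because the baseline is tie-break-sensitive; search
optimum 0.4198 with 4 communities over 50 restarts), the full 20-cell
strategy grid at 20 restarts per cell, exhaustive set-partition oracles on
50 random connected graphs with up to 8 nodes, $10^4$ randomized
incremental-consistency moves on graphs with up to 50 nodes, and a
$\mu \in \{0.1, \dots, 0.4\}$ sweep at $n = 250$ with 5 seeds per value.
These sizes keep a full run in the minutes range while leaving each claim
statistically meaningful.

## Known limitations

* The incremental state keeps a dense $n \times n$ inter-community edge
  matrix: simple and fast at benchmark scales ($n$ up to a few thousand),
  wrong tool for millions of nodes.
* Only undirected, unweighted simple graphs are supported.
* The greedy baseline's exact final value depends on tie-breaking; only
  the deterministic smallest-pair rule is provided.
* Escape-schedule constants (two node kicks; community kick every fourth
  escape) were fixed from the karate landscape analysis; they are not
  exposed as configuration and other networks might prefer different
  schedules.
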