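# dgmod — greedy modularity community detection with disassembly exploration

`dgmod` detects communities (modules) in undirected, unweighted networks —
protein–protein interaction graphs, metabolic networks, social networks —
by modularity maximization. It implements the classic
Clauset–Newman–Moore (CNM) greedy agglomeration and augments it with
stochastic *disassembly* exploration moves that break nodes or whole
communities back apart so the greedy phase can rebuild them better,
escaping the local optima that plain CNM stops in.

## The method in brief

For a partition $S$ of a graph with $L$ edges, modularity is

$$Q(S) = \sum_{c \in S}\left(\frac{l_c}{L} - \left(\frac{k_c}{2L}\right)^2\right),$$

with $l_c$ the edges inside community $c$ and $k_c$ its summed degree.
Greedy exploitation repeatedly applies the merge with the largest gain
$\Delta Q = 2(e_{ij} - a_i a_j)$. Exploration fires with probability 5%
per iteration for each move family (configurable): a *node disassembly*
(pull one node out; split the remainder into components) or a *community
disassembly* (dissolve a community into singletons), with targets picked
at random or by quality criteria — weak nodes/communities, low
embeddedness, low internal edge density, low triad participation,
high conductance. The search runs $30\,n$ iterations (configurable),
tracks the best partition ever seen, and supports independent seeded
restarts. Partition agreement is measured by normalized mutual
information (NMI); planted-partition benchmark graphs with power-law
degrees and community sizes and a tunable mixing parameter µ are
generated in-package. See `vignette("dgm-methods")` for the model,
parameter meanings and design rationale.

## Worked example

```r
library(dgmod)

karate <- load_fixture("karate")          # Zachary karate club, 34 nodes / 78 edges
modularity_q(karate$graph, karate$reference)
#> [1] 0.3582347                            # the two observed factions

run_greedy(karate$graph)$q                # plain CNM baseline
#> [1] 0.3806706                            # 3 communities, a local optimum

res <- run_dgm(karate$graph,
               dgm_config(community_strategy = "weak",
                          node_strategy = "random",
                          seed = 1, n_restarts = 10))
res
#> <dgm_result> best Q = 0.4198, 4 communities (weak community / random node, 10 restarts)
nmi(res$best_partition, karate$reference)
#> [1] 0.5878497
```

The disassembly search lifts the karate modularity from the greedy 0.3807
(3 communities) to 0.4198 — the network's global optimum, with 4
communities: exploration splits the factions into their known
sub-communities. The NMI of 0.59 against the two-faction labels reflects
that refinement: the four modules are sub-divisions of the factions, not
a disagreement about the split.

A command-line interface wrapping the same functions ships in
`inst/cli/dgm`:

```sh
inst/cli/dgm detect --input inst/extdata/karate.edgelist \
    --community-strategy weak --node-strategy random \
    --seed 1 --restarts 10 --output membership.tsv
# best_Q=0.4198 communities=4
```

Subcommands: `greedy`, `detect`, `grid` (all 20 strategy combinations),
`evaluate` (NMI between membership files), `metrics` (per-community
quality table), `synth` and `sweep` (planted benchmarks). Every file-writing
run also writes a JSON manifest with the resolved configuration and input
digests for reproducibility.

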