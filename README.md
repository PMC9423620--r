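# carank — community-aware ranking of influential nodes

Centrality measures are the standard tool for picking influential spreaders
in a network, but the classical recipe — sort all nodes by score, take the
top *B* — routinely selects nodes that sit next to each other in one dense
region, wasting the budget on overlapping zones of influence. `carank`
implements a simple, measure-agnostic alternative for networks with
community structure: order the communities from largest to smallest, then
take each community's best node in turn, round-robin, until the budget is
filled. Seeds end up scattered across every dense region of the graph.

The package is aimed at anyone running diffusion or immunization
experiments on networks — epidemic modelling, information spreading,
marketing-seed selection — and provides the full evaluation apparatus
around the scheme:

* **Ranking** — `descending_rank()` (classical) and `community_aware_rank()`
  (community by community), both with seeded uniform tie-breaking.
* **Centralities** — `compute_centrality()` with `degree`, `mnc` (maximum
  neighborhood component), `betweenness` (exact), `closeness`
  (per-component), `katz` and `pagerank`.
* **Spreading** — a discrete-time synchronous SIR simulator
  (`simulate_sir()`, Rcpp core), the epidemic-threshold estimate
  ⟨k⟩/(⟨k²⟩−⟨k⟩), and the gain statistic
  `delta_r()`: ΔR = 100·(R̄_CA − R̄_DO)/n, the extra share of the network
  reached when seeds are community-aware rather than taken top-down.
* **Benchmark graphs** — `generate_lfr()`, an LFR-style generator with
  power-law degrees and community sizes and a tunable mixing parameter μ,
  plus `generate_planted_partition()` for controlled fixtures.
* **I/O and orchestration** — plain-text edge-list/GML/partition readers,
  `run_experiment()` sweeps over measures and seeding fractions with full
  manifests, and a thin command-line wrapper (`inst/cli/carank.R`).

## Worked example

The bundled 22-node toy network has three communities (sizes 9 > 7 > 6) and
the three highest-degree nodes all in the largest community:

```r
library(carank)
toy <- toy_example()

community_aware_rank(toy$degree, toy$partition, budget = 3)
#> ranked list (community_aware, degree): budget 3
#> [1] "5"  "13" "19"

descending_rank(toy$degree, budget = 3)
#> ranked list (descending, degree): budget 3
#> [1] "5" "4" "1"
```

The descending scheme spends the whole budget inside one community (nodes
5, 4, 1); the community-aware scheme picks each community's leader (5, 13,
19). On a benchmark graph, that difference translates into a measurably
larger epidemic outbreak:

```r
net <- generate_lfr(mu = 0.05, rng_seed = 7)   # 2500 nodes, strong communities
sc  <- compute_centrality(net$graph, "degree")
delta_r(net$graph, sc, net$partition, f_o = 0.15, runs = 500, rng_seed = 7)
#> deltaR = +16.84% (se 0.07) at f_o = 0.15 (budget 375, lambda 0.1088)
```

Seeding the top 15% of nodes community-aware instead of top-down reaches an
extra ~17% of the 2500-node network, at a threshold-calibrated infection
probability. The gain shrinks as μ grows (weaker communities) — that
dependence, and the influence of the community-size and degree exponents,
is exactly what the benchmark suite quantifies.

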