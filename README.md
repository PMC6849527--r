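# dispnet

Frugivory is not seed dispersal. Plant–frugivore networks are usually
sampled as *visitation* networks — counts of birds foraging on fruiting
plants — but a visit can be a mutualistic seed-dispersal event (the bird
swallows the fruit and moves viable seeds), pulp pecking (the bird eats
pulp, the seed drops under the parent) or seed predation (the bird destroys
the seed). dispnet is for ecologists who want to know how much this
distinction matters: it labels every link of a quantitative bipartite
network with its functional outcome, prunes the non-mutualistic links, and
quantifies the structural consequences at the network and species level.

The package implements:

* a labelled-network data model with edge-list and adjacency-matrix I/O,
  rate-to-count conversion, and outcome inference from congeners and fruit
  traits;
* weighted network metrics — size *S*, weighted connectance
  *LD*/*S* with *LD* the marginal-weighted mean effective partner number
  exp(*H*), weighted nestedness WNODF, specialization *H₂′* =
  (*H₂ₘₐₓ* − *H₂*)/(*H₂ₘₐₓ* − *H₂ₘᵢₙ*), and weighted Barber modularity
  *Q* = (1/m) Σᵢⱼ (aᵢⱼ − AᵢAⱼ/m) δ(gᵢ, hⱼ) maximized by a
  label-propagation + agglomeration (LPAwb+-style) search;
* species metrics — degree, interaction frequency, specialization *d′*
  (standardized Kullback–Leibler deviation of partner use from
  availability) and species strength Σᵢ aᵢⱼ/Aᵢ;
* Patefield and fill-conserving quasiswap quantitative null models with
  Δ-transformation (observed minus null mean);
* a topological coextinction model: birds removed from least to most
  frequent, plants failing after losing ≥ 75% of their interaction
  frequency, robustness as the area under the survival curve and per-plant
  Resilience₇₅;
* one-tailed paired Wilcoxon (exact to n = 25) and Spearman (exact to
  n = 8) tests, the exact Bernoulli-process multiple-test probability
  *p* = C(N, K) αᴷ (1 − α)ᴺ⁻ᴷ, and summary change tables;
* a seeded generator of realistic labelled visitation networks, so the
  full pipeline is testable without any data download.

## Worked example

```r
library(dispnet)

net <- generate_network(synthetic_config(), seed = 7, network_id = "demo")
net
#> Labelled visitation network 'demo'
#>   20 plants x 25 birds, 228 links, total frequency 1754
#>   links: 158 seed dispersal, 21 pulp pecking, 49 seed predation

pr <- prune(net, "all_nonmutualistic")
network_size(net); network_size(pr$pruned)
#> 45 -> 36            # 9 birds had no seed-dispersal link at all
weighted_connectance(net); weighted_connectance(pr$pruned)
#> 0.1696 -> 0.1929    # connectance rises as size falls
weighted_nodf(net); weighted_nodf(pr$pruned)
#> 44.26 -> 51.67      # the mutualistic backbone is more nested
robustness(simulate_coextinction(net))
robustness(simulate_coextinction(pr$pruned))
#> 0.924 -> 0.881      # less redundancy once exploiters are gone
```

The numbers say: treating this visitation network as a seed-dispersal
network would overstate its size and its robustness to bird loss, and
understate its nestedness — exactly the biases the pruning analysis is
designed to expose. `run_analysis(run_config(...))` chains the whole
pipeline (prune → metrics → null models → coextinction → paired tests)
over an ensemble of networks and writes tidy CSV tables plus a seed log;
`moran_probability(6, 4, 0.05)` (= 8.46e-05) is the guard against reading
a batch of significant one-tailed tests as a multiple-testing artefact. A
thin command-line wrapper with the same options ships in `inst/cli/`.

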