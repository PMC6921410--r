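# starclus

Ranking-based clustering of star-schema heterogeneous information networks.

## What problem this solves

Many biomedical knowledge bases are naturally *star networks*: a single
target object type linked, with weighted edges, to several attribute types —
and nothing else.  The motivating case is traditional Chinese medicine,
where a **formula** (a multi-herb prescription) links to the **herbs** it
contains, the **functions** it is ascribed, and the **symptoms** it treats.
Practitioners mining such data want two coupled outputs: a partition of the
formulas into `K` coherent categories, and, inside every category, a ranking
of the objects of *each* type — so a cluster is a profile ("these formulas,
dominated by these herbs, for these symptoms"), not just a set.

`starclus` is for researchers who have such an edge list (or want to study
the method itself) and need a self-contained, reproducible implementation
with a synthetic benchmark and an accuracy metric built in.

## The method

For each attribute type, the network decomposes into a bipartite relation
matrix `W` (targets × attributes, entries = aggregated link weights).
Importance propagates by mutual reinforcement — highly ranked targets link
to highly ranked attributes and vice versa — so, with L1 normalization, the
attribute ranking is the principal eigenvector of

    M = α · WᵀW + (1 − α) · W_SS,        W_SS = Wᵀ W,

computed by the power method, and the target ranking is the normalized image
`W · p(attribute)`.  Given a partition, each cluster's induced subnetwork
yields *conditional* rankings, smoothed against the global ranking
(Jelinek–Mercer, weight `λ`).  Treated as visit probabilities, these define
a generative mixture for each bipartite network whose cluster priors
`p(z = k)` are estimated by EM; Bayes' rule then gives each target a
posterior membership row `Θ[i, k] ∝ p(x_i | k) · p(z = k)` per network.
Concatenating the rows across the `A` networks embeds every target in
`A · K` dimensions; cluster centers are member means and targets re-assign
to the nearest center by cosine distance until the partition stabilises.
Multiple random restarts are scored by the summed model log-likelihood.
Optional soft seeds (`target → cluster`, confidence `λ_d`) blend a Dirichlet
prior into the posterior rows.  Accuracy against a known partition is
measured by FVIC, the fraction of vertices identified correctly:

    FVIC = Σ_{c ∈ found} max_{c* ∈ known} |c ∩ c*| / N.

## Worked example

```r
library(starclus)

sim <- simulate_star_network(K = 3, targets_per_cluster = 30,
                             attrs_per_cluster = 15, links_per_type = 5,
                             noise = 0.05, rng_seed = 1)
res <- cluster_star_network(sim$network, K = 3, rng_seed = 1)
res
#> <star_clustering> K = 3 | cluster sizes: 30, 30, 30
#>   outer iterations: 3 | converged: TRUE
#>   assignment changes: 46 2 0

fvic(as_partition(res$assignment), sim$truth)
#> [1] 1
```

Three planted clusters of 30 formulas are generated with 5% cross-cluster
noise; the algorithm converges in three outer iterations (46 then 2 then 0
targets change cluster) and recovers the planted partition exactly
(FVIC = 1).  Within-cluster rankings are available per type:

```r
head(sort(res$cluster_rankings[[1]]$herb$probs, decreasing = TRUE), 5)
#> herb_c1_05 herb_c1_09 herb_c1_15 herb_c1_12 herb_c1_14
#> 0.13146192 0.08783905 0.08339635 0.06784153 0.05987952
```

— the top-ranked herbs of cluster 1 all come from the planted vocabulary of
cluster 1, with ranks summing to 1 over the full herb registry.

## Command line

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "starclus", package = "starclus"))')
Rscript $CLI simulate --k 3 --noise 0.05 --seed 1 --output edges.tsv --truth truth.tsv
Rscript $CLI cluster  --input edges.tsv --k 3 --seed 42 --output result.json
Rscript $CLI evaluate --result result.json --truth truth.tsv
Rscript $CLI rank     --input edges.tsv --alpha 0.8 --output-dir ranks/
```

Edge files are UTF-8 TSV (`target_id  attribute_type  attribute_id  weight`,
weight optional, `#` comments allowed); truth/seed files are
`target_id  cluster_index` with 0-based indices.

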