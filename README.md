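# barcodiv

Species richness estimation and species delimitation from mitochondrial
barcode sequences (*cox1*-style protein-coding fragments), with the
evaluation statistics used to score molecular groups against a
morphology-based taxonomy, and a coalescent simulator that makes the whole
pipeline testable with known truth.

Biodiversity surveys increasingly substitute mtDNA sequencing for scarce
taxonomic expertise: cluster the sequences, count the groups, treat them
as species. `barcodiv` is for researchers who want to run that analysis
*and* quantify how well it works — including its characteristic failure
mode, recently diverged species that are non-monophyletic in the
mitochondrial gene tree because lineage sorting is incomplete.

## What it implements

**Delimitation methods**

* *Fixed-threshold clustering* — uncorrected p-distances with pairwise
  deletion; clusters are connected components under single-linkage
  chaining (if d(A,B) ≤ t and d(B,C) ≤ t, then A, B, C are one cluster
  even when d(A,C) > t). `cluster_at_threshold()`, `threshold_sweep()`.
* *Single-threshold GMYC* — the generalized mixed Yule–coalescent model
  on an ultrametric gene tree. Branching intensity in each inter-event
  interval is b = λ₁·d^p₁ + λ₂·Σⱼ [mⱼ(mⱼ−1)]^p₂, with d the lineages
  above the threshold T (the entity count below it) and mⱼ the lineages
  inside below-threshold subtree j. T is profile-maximized over
  candidate heights; a χ² (df = 3) likelihood-ratio test compares against
  the single-process null b = λ·n^p. `fit_gmyc()`, with broom-style
  `tidy()` / `glance()` and `autoplot()`.
* *Statistical-parsimony networks* — haplotypes linked when their Hamming
  distance is within a connection limit derived from a single-hit
  probability model at 95% parsimony probability (or a user-supplied
  limit); components are species surrogates. `delimit_networks()`.
* *Population aggregation analysis (PAA)* — fixed diagnostic sites
  between groups (disjoint observed state sets), and pairwise
  step-addition merging of non-diagnosable groups. `diagnostic_sites()`,
  `paa_aggregate()`.

**Evaluation and diversity statistics**

* `evaluate_partition()` — *agreement* (100·groups/species, may exceed
  100) and *taxonomic accuracy* (100·perfect groups/species, a perfect
  group holding all individuals of exactly one species), plus
  split-species and lumped-group counts.
* `barcoding_gap_table()` — largest intraspecific vs smallest congeneric
  interspecific p-distance per species.
* `sorensen()` / `distance_decay()` — S = 2C/(A+B) between regional
  assemblages under one pooled partition, and its OLS slope on distance.
* `shared_group_pct()`, `report_summary()` — shared-group percentages and
  mean/population-SD/median summary rows as survey tables print them.

**Synthetic data with known truth** — `simulate_dataset()` draws a Yule
species tree, a multispecies-coalescent gene tree, stop-codon-free
protein-coding sequences at the standard insect mitochondrial rate (2.3%
pairwise divergence per Ma), skewed specimen sampling with singletons,
and regional ranges with distance decay. Scenario knobs force a recent
radiation (incomplete lineage sorting → non-monophyly → lumping) or a
well-separated "old fauna" (all methods should recover the species count
essentially exactly). `run_pipeline()` orchestrates
simulate → delimit → evaluate → β-diversity deterministically under one
seed.

## Worked example

```r
library(barcodiv)

# 20 well-separated species, coalescent depth << species divergences
d <- simulate_dataset(sim_config(n_species = 20, coal_depth = 0.1,
                                 min_split_age = 2, seed = 7))
d
#> Synthetic barcode dataset
#>   species: 20  specimens: 120  sites: 828
#>   regions: 6  seed: 7

dm <- p_distance_matrix(d$alignment)
clusters <- cluster_at_threshold(dm, 3)     # 3% threshold
evaluate_partition(clusters, d$truth)
#> # A tibble: 1 x 9
#>   n_species n_groups n_perfect n_species_split n_groups_lumped agreement_pct ...
#> 1        20       20        20               0               0           100

fit <- fit_gmyc(d$gene_tree)
glance(fit)
#> # A tibble: 1 x 10
#>   n_tips n_entities threshold  logL logL_null    LR  p_value  ci_n ci_min ci_max
#> 1    120         21     0.401  547.      499.  96.4 9.30e-21     2  0.401   1.30

gap_summary(barcoding_gap_table(dm, d$truth))
#> # A tibble: 2 x 5
#>   statistic                n  median    mean      sd
#> 1 max_intra               15 0.00483 0.00467 0.00363
#> 2 min_inter_congeneric    16 0.0767  0.0859  0.0333
```

Reading the output: clustering at 3% recovers all 20 species as perfect
clusters (agreement and accuracy both 100). GMYC places its threshold at
0.40 Ma — between the within-species coalescences (median largest
intraspecific distance 0.5%) and the species splits (median smallest
congeneric distance 7.7%) — delimits 21 entities (one species split in
two, a typical mild oversplit), and rejects the null single-process model
decisively (LR = 96.4 against χ²₃). Adding
`radiation = list(n_species = 8, age = 0.3)` to the config makes the
radiation species non-monophyletic and drives accuracy below 100 for
every method; `plot_threshold_sweep(threshold_sweep(dm, d$truth))` draws
the classic agreement/accuracy curves across 1–10% thresholds.

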