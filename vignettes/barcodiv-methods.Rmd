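---
title: "Species delimitation and richness estimation from mitochondrial barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation and richness estimation from mitochondrial barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Large-scale biodiversity surveys routinely sequence a short mitochondrial
protein-coding fragment (a *cox1*-style barcode) for hundreds or thousands
of specimens and ask: how many species are present, and how well do
molecular groups match species delimited by morphology? `barcodiv`
implements the standard toolkit for this question — fixed-threshold
p-distance clustering, single-threshold GMYC delimitation on an
ultrametric gene tree, statistical-parsimony network membership, and
character-based population aggregation analysis (PAA) — together with the
evaluation statistics used to score any of these against a morphospecies
reference, and Sørensen β-diversity across regions. A
coalescent-within-species-tree simulator generates synthetic barcode
datasets with known truth so the entire pipeline is testable end to end.

Two performance metrics are used throughout. For an estimated partition of
the specimens into groups (clusters, GMYC entities, networks, PAA
aggregates) and a morphospecies truth with $S$ species:

* **agreement** (species-richness-estimation success) $= 100\,G/S$, where
  $G$ is the number of estimated groups; it may exceed 100 when the
  estimate oversplits;
* **taxonomic accuracy** $= 100\,P/S$, where $P$ counts *perfect* groups —
  groups containing all sequenced individuals of exactly one species and
  no others.

A *split* species is spread over two or more groups; a *lumped* group
contains two or more species. Accuracy never exceeds agreement... more
precisely, since $P \le G$ and both are scaled by the same $S$,
`accuracy_pct <= agreement_pct` holds on every input, and the test suite
asserts it as an invariant.

# Distance clustering

`p_distance_matrix()` computes uncorrected p-distances (proportion of
differing sites), with pairwise deletion of sites carrying an N in either
sequence. `cluster_at_threshold()` forms the connected components of the
graph with an edge wherever $d \le t$: single-linkage chaining, so that if
A–B and B–C are within the threshold but A–C is not, all three still join
one cluster. Thresholds may be given as fractions (0.03) or percent (3).
`barcoding_gap_table()` reports, per species, the largest intraspecific
distance and the smallest interspecific distance to a congeneric species
(genus = first whitespace token of the species name); the overlap of these
two distributions is what decides whether any fixed threshold can work.

Design notes: pairwise (not complete) deletion is used for ambiguous
sites, switchable only by pre-filtering the alignment; summary standard
deviations use the population convention (divisor $n$), which is what
published survey tables of this kind print; percentages are reported at
full precision together with half-away-from-zero rounded columns, because
printed tables round that way.

# Single-threshold GMYC

The generalized mixed Yule–coalescent model locates a time threshold $T$
on an ultrametric gene tree separating between-species branching (older
than $T$, speciation-like) from within-species branching (younger than
$T$, coalescent-like). Tips hanging below $T$ in one subtree form one
*entity* (species hypothesis); terminal branches crossing $T$ are
singleton entities.

## Likelihood

Inter-event intervals are taken between successive branching events
ordered from the tips, the coalescent convention: each interval is
terminated by the event at its older end, and rates are evaluated with the
lineage counts during the interval. In the interval $k$ of duration $x_k$
the total branching intensity is

$$ b_k \;=\; \lambda_1\, d_k^{\,p_1} \;+\; \lambda_2 \sum_j
   \left[m_{j,k}(m_{j,k}-1)\right]^{p_2}, $$

where $d_k$ counts lineages whose subtending branch segment lies above
$T$ — the full lineage count in intervals above $T$, and the constant
number of entities in intervals below $T$ (their stems cross $T$; the
diversification process persists there without observed events) — and
$m_{j,k}$ counts the lineages inside below-threshold subtree $j$
(singleton groups contribute zero, as $m(m-1)=0$). Each interval
contributes $\log b^{(e)}_k - b_k x_k$, with the event term
$b^{(e)}_k$ the component of $b_k$ belonging to the process in which the
terminating event occurs; $T$ splits the interval it falls in, and the
interval touching the present has no event term.

Three consequences are worth stating because they are checked by tests:
at $T = 0$ the model reduces *exactly* to the null single-process model
$b = \lambda n^p$, so the null is nested and the likelihood ratio is
non-negative by construction; at $T$ above the root it reduces to the
single-group Kingman-style coalescent (rate
$\lambda_2 [n(n-1)]^{p_2}$, which for $p_2 = 1$,
$\lambda_2 = 1/(2\theta)$ is the standard coalescent likelihood); and the
event terms are process totals, not per-group rates, so model and null
are densities over the same observable (the event times) and their
likelihoods are comparable.

## Fitting

Candidate thresholds are midpoints between consecutive distinct node
heights, plus a candidate below the youngest node (every tip its own
entity; the near-null limit) — ties between equal profile maxima break
toward the older threshold. Given $T$ the likelihood separates into a
$(\lambda_1, p_1)$ term and a $(\lambda_2, p_2)$ term, and within each the
rate has a closed-form profile MLE given the exponent
($\hat\lambda = E/\sum_k S_k(p) x_k$ with $E$ the event count). Each
exponent is therefore maximized by a one-dimensional profile search: a
31-point grid on $[0, 3]$ refined by `optimize()` in the best bracket.
This replaces a 4-parameter multi-start box search: it is deterministic,
cannot miss the optimum of the 1-D profile by more than the grid
resolution, and is what makes fitting hundreds of replicate trees cheap.
Rates are bounded in $[10^{-8}, 10^4]$ and exponents in $[0, 3]$.

The likelihood-ratio test compares the fitted mixed model against the
single-process null with a $\chi^2_3$ reference (four parameters against
two; the threshold, an argmax over a finite candidate set, is not
counted — `df` is an argument for users who prefer a different
convention). On single-species coalescent trees of 40 tips the empirical
size at $\alpha = 0.05$ is about 4–5% (recomputed by
`scripts/acceptance.R`), so with this construction the test is close to
nominal rather than anticonservative. The threshold confidence set
contains every candidate within 2 log-likelihood units of the maximum.

## Preprocessing

GMYC requires a fully dichotomous ultrametric tree with positive branch
lengths. `preprocess_tree()` resolves polytomies (zero-length branches),
verifies ultrametricity to a relative tolerance of $10^{-6}$, collapses
zero-height clades — identical haplotypes — to their lexicographically
smallest tip while recording an alias map (entities are re-expanded to
all specimens after fitting), and separates residual coincident node
heights multiplicatively by a relative offset of $10^{-8}$ of the root
height.

# Statistical-parsimony networks

Haplotypes (exact-match collapsed sequences) are connected when their
Hamming distance is at most a *connection limit*; network membership is
the connected components, expanded back to specimens. The classical
recursion for the 95% limit is not reproduced here; instead a
self-contained single-hit model defines it: for $j$ observed differences
over $L$ sites, the per-site substitution intensity $\mu$ is estimated by
a Jukes–Cantor-style correction of $j/L$, the probability that a changed
site changed exactly once is $\mu e^{-\mu}/(1-e^{-\mu})$ (Poisson hit
counts), and the limit is the largest $j$ with
$[\mu e^{-\mu}/(1-e^{-\mu})]^j \ge 0.95$ (computed in log space). For an
828 bp fragment this gives 9 steps, somewhat stricter than published
implementations of the recursion; `delimit_networks(limit = )` overrides
the limit to match a published analysis, since network membership depends
on it.

# Population aggregation analysis

`diagnostic_sites()` lists alignment columns where the observed state
sets of two groups are non-empty and disjoint (Ns excluded by default; a
wildcard mode treats N as intersecting everything). This is the strict
fixed-difference notion of diagnosability: two groups diverging by well
under any clustering threshold can still be diagnosable by a single fixed
site. `paa_aggregate()` performs pairwise step addition: repeatedly merge
the closest non-diagnosable pair of groups (smallest mean between-group
p-distance; ties by the alphabetically smallest label pair, and the
merged group keeps the smaller label) until all remaining pairs are
mutually diagnosable. The merge order is fixed because the end state can
be order-dependent; the chosen order is deterministic and documented
rather than left to input order.

# β-diversity

`sorensen()` computes $S = 2C/(A+B)$ between two regional assemblages,
where $A$ and $B$ count groups present in each region and $C$ the groups
present in both. Presence is always read off **one pooled partition** of
all the data restricted to each region: "shared" is only well-defined
inside a common partition, and per-region re-clustering can delimit
incompatible groups (re-cluster the subsets yourself and compare if you
want that sensitivity check). `distance_decay()` fits an OLS slope of $S$
on between-region distance.

# The synthetic-data generator

`simulate_dataset()` draws, under one seed: a Yule species tree
conditioned on the species count and rescaled to a crown age; a
multispecies-coalescent gene tree (within each species $k$ lineages
coalesce at rate $\binom{k}{2}/\theta$, with $\theta$ = `coal_depth` the
expected pairwise within-species coalescence time; unsorted lineages
enter the ancestral species); protein-coding sequences evolved down the
gene tree under a K2P-style process with stop-codon rejection
(invertebrate mitochondrial code; the root is drawn from stop-free
codons, so simulated alignments always pass `qc_translate()`); and a
regional occupancy model (contiguous ranges with geometric size on a line
of regions) that induces distance decay of shared species.

Default parameters emulate a continental insect barcode survey: 40
species, crown age 35 Ma, within-species coalescent depth 0.5 Ma, 828 bp
evolving at 2.3% pairwise divergence per Ma of separation (per-lineage
rate half of that), transition/transversion ratio 4, sampling with mean
4.8 specimens per species (capped at 32) and 10% forced singletons, six
regions 500 km apart, and genera defined as clades younger than 10 Ma.
Under these defaults the median largest intraspecific distance sits near
1.7% and the median smallest congeneric interspecific distance near 8%,
i.e. mostly-separated distributions with an overlapping tail — the
structure the analysis methods are designed for. The crown age and
coalescent depth were chosen once to land in those bands and then frozen.

Two scenario knobs deserve explanation:

* `radiation = list(n_species =, age =)` grafts a clade whose internal
  divergences all postdate `age`. With `age` far below `coal_depth`,
  lineage sorting is incomplete, the radiation species are
  non-monophyletic in the gene tree, and every delimitation method lumps
  them — the lineage-idiosyncratic error mode that dominates real
  surveys.
* `min_split_age` linearly rescales the base tree's speciation times into
  `[min_split_age, crown_age]`, emulating a clade whose diversification
  slowed down so all species are old. This exists because a
  crown-conditioned Yule tree always carries some very recent sister
  splits ($\lambda t$ is pinned near $\ln(n/2)$ by the conditioning), so
  "all species well separated" is not reachable by tuning rates alone;
  it is the scenario in which threshold clustering should recover the
  species count essentially exactly, and the recovery tests use it.

What the generator does **not** emulate: introgression and migration,
nuclear pseudogenes (numts), among-site and among-lineage rate variation,
indels, sequencing error, and — deliberately — gene-tree *inference*: the
GMYC stage consumes the simulator's true ultrametric gene tree, isolating
the delimitation model from branch-length-estimation error. Passing tests
therefore certify the methods' behavior under clean coalescent
expectations, not robustness to those real-data complications.

# Numerical and convention choices

* Ultrametricity tolerance $10^{-6}$ (relative); zero-branch separation
  offset $10^{-8}$ of the root height; identical-haplotype detection at
  $10^{-9}$ of the root height.
* Cluster and network labels are assigned in order of each group's
  smallest member id, so partitions are invariant to input record order.
* Percentages round half away from zero (`round_half_up()`), matching how
  survey tables print them; full-precision values are always kept
  alongside. Published tables of this kind are not perfectly consistent
  (some cells are truncated instead); the package computes from counts
  and does not reproduce such inconsistencies.
* `evaluate_partition()` errors on any specimen-coverage mismatch rather
  than silently intersecting.
* Degenerate inputs: a single-tip tree is a valid simulation output;
  GMYC requires at least 3 distinct haplotypes; a pair of sequences with
  no comparable (non-N) sites is an error naming the pair.

# Problem sizes

The test-suite and acceptance-script simulations use 20-species,
roughly 100-specimen datasets with 25–50 replicates for recovery and
calibration properties, and the 40-species default dataset for
single-dataset statistics. These sizes give Monte-Carlo error well inside
the asserted bounds (e.g. a true recovery rate of 1.0 cannot fail a
$\ge 0.9$ bound at $n = 50$; a true test size of 5% fails a 20% bound
with negligible probability) while keeping a full run to a few minutes.

# Limitations

The GMYC implementation is single-threshold only. Tree inference,
corrected distances (K2P/GTR), Bayesian delimitation, and information-
theoretic partition distances are out of scope. The connection-limit
model is a deliberate simplification of the classical recursion; use the
`limit` override for strict comparability with published network counts.
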