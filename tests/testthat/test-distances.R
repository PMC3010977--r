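test_that("stop-codon QC flags internal stops and passes clean sequences", {
  # ATG GCT = Met Ala under the invertebrate mitochondrial code: clean
  aln <- toy_alignment(c("ATGGCT", "ATGGCT"))
  qc <- qc_translate(aln)
  expect_true(all(qc$pass))

  # internal TAA is flagged at its codon index; a terminal stop is ignored
  aln2 <- toy_alignment(c("ATGTAAGCTTAA"))
  qc2 <- qc_translate(aln2)
  expect_false(qc2$pass[1])
  expect_equal(qc2$stop_codons[[1]], 2L)

  expect_error(qc_translate(toy_alignment("AC")), "translate")
})

test_that("p-distances match the definition and a per-site oracle", {
  aln <- toy_alignment(c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAAAA"))
  dm <- p_distance_matrix(aln)
  expect_equal(dm[1, 3], 0)
  expect_equal(dm[1, 2], 0.1)
  expect_true(isSymmetric(dm))

  # N sites are pairwise-deleted
  alnN <- toy_alignment(c("NAAAAAAAAC", "CAAAAAAAAA"))
  expect_equal(p_distance_matrix(alnN)[1, 2], 1 / 9)

  # a pair with no comparable sites is an error naming the pair
  alnZ <- toy_alignment(c("NNAC", "ACNN", "ACAC"))
  expect_error(p_distance_matrix(alnZ), "no comparable sites")

  set.seed(401)
  aln_r <- random_alignment(12, 60, n_frac = 0.05)
  dm_r <- p_distance_matrix(aln_r)
  for (k in 1:50) {
    ij <- sample.int(12, 2)
    expect_equal(
      dm_r[ij[1], ij[2]],
      p_dist_site_loop(aln_r$sequence[ij[1]], aln_r$sequence[ij[2]]),
      tolerance = 1e-12
    )
  }
})

test_that("threshold clustering chains through intermediates (A-B-C)", {
  dm <- matrix(c(0, 0.02, 0.04,
                 0.02, 0, 0.02,
                 0.04, 0.02, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  part <- cluster_at_threshold(dm, 0.03)
  expect_equal(length(unique(part$group)), 1L)
  # same in percent notation
  expect_equal(partition_as_groups(cluster_at_threshold(dm, 3)),
               partition_as_groups(part))
  # without the bridge, A and C separate
  part2 <- cluster_at_threshold(dm[c("A", "C"), c("A", "C")], 0.03)
  expect_equal(length(unique(part2$group)), 2L)
})

test_that("clustering equals brute-force union-find on random matrices", {
  set.seed(402)
  for (rep in 1:100) {
    n <- sample(3:50, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.2)
    d <- d + t(d)
    ids <- sprintf("s%03d", sample.int(999, n))
    dimnames(d) <- list(ids, ids)
    t <- runif(1, 0, 0.15)
    got <- partition_as_groups(cluster_at_threshold(d, t))
    want <- canonical_groups(uf_cluster(d, t))
    expect_equal(got, want)
  }
})

test_that("clustering is invariant to input record order", {
  set.seed(403)
  aln <- simulate_dataset(sim_config(n_species = 8, seed = 21))$alignment
  dm <- p_distance_matrix(aln)
  perm <- sample(nrow(dm))
  dmp <- dm[perm, perm]
  expect_equal(partition_as_groups(cluster_at_threshold(dm, 0.03)),
               partition_as_groups(cluster_at_threshold(dmp, 0.03)))
})

test_that("threshold sweep is monotone and saturates at one cluster", {
  d <- simulate_dataset(sim_config(n_species = 10, seed = 9))
  dm <- p_distance_matrix(d$alignment)
  sweep <- threshold_sweep(dm, d$truth, thresholds = seq(0.01, 0.10, 0.01))
  expect_true(all(diff(sweep$n_groups) <= 0))
  expect_true(all(sweep$accuracy_pct <= sweep$agreement_pct + 1e-9))

  # a full-merge threshold leaves a single cluster
  one <- cluster_at_threshold(dm, 1.0)
  expect_equal(length(unique(one$group)), 1L)

  # at t = 0 only identical sequences merge
  zero <- cluster_at_threshold(dm, 0)
  haps <- collapse_haplotypes(d$alignment)
  expect_equal(length(unique(zero$group)), nrow(haps))
})

test_that("well-separated simulations cluster perfectly at 3%", {
  d <- simulate_dataset(recovery_config(7))
  dm <- p_distance_matrix(d$alignment)
  ev <- evaluate_partition(cluster_at_threshold(dm, 0.03), d$truth)
  expect_equal(ev$accuracy_pct, 100)
  expect_equal(ev$agreement_pct, 100)
})

test_that("barcoding-gap table handles singletons, monotypic genera and bands", {
  # two singleton congeners: no intra, inter = their distance
  aln <- toy_alignment(c("AAAAAAAAAA", "CCAAAAAAAA", "GGGGGAAAAA"),
                       species = c("Gen a", "Gen b", "Other c"))
  dm <- p_distance_matrix(aln)
  gap <- barcoding_gap_table(dm, morphospecies_partition(aln))
  expect_true(all(is.na(gap$max_intra)))
  expect_equal(gap$min_inter_congeneric[gap$species == "Gen a"], 0.2)
  expect_true(is.na(gap$min_inter_congeneric[gap$species == "Other c"]))

  # default simulation falls in the documented divergence bands
  d <- simulate_dataset(sim_config(seed = 31))
  dm_d <- p_distance_matrix(d$alignment)
  gap_d <- barcoding_gap_table(dm_d, d$truth)
  s <- gap_summary(gap_d)
  expect_lt(s$median[s$statistic == "max_intra"], 0.03)
  expect_gt(s$median[s$statistic == "min_inter_congeneric"], 0.05)
})

test_that("removing the radiation clade shifts smallest congeneric distances up", {
  d <- simulate_dataset(radiation_config(13))
  dm <- p_distance_matrix(d$alignment)
  gap_all <- barcoding_gap_table(dm, d$truth)
  keep <- !(d$alignment$species %in% d$radiation_species)
  aln_clean <- d$alignment[keep, ]
  gap_clean <- barcoding_gap_table(p_distance_matrix(aln_clean),
                                   morphospecies_partition(aln_clean))
  expect_gt(median(gap_clean$min_inter_congeneric, na.rm = TRUE),
            median(gap_all$min_inter_congeneric, na.rm = TRUE))
})
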