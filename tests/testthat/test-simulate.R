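test_that("identical config and seed give a bit-identical dataset", {
  cfg <- sim_config(n_species = 10, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$alignment, d2$alignment)
  expect_identical(d1$region_map, d2$region_map)
  expect_identical(ape::write.tree(d1$gene_tree), ape::write.tree(d2$gene_tree))
  expect_identical(ape::write.tree(d1$species_tree),
                   ape::write.tree(d2$species_tree))
})

test_that("species tree honours species count, crown age and radiation block", {
  set.seed(1)
  cfg <- sim_config(n_species = 25, crown_age = 35, seed = 1)
  tr <- simulate_species_tree(cfg)
  expect_equal(ape::Ntip(tr), 25L)
  expect_equal(max(node_heights(tr)), 35, tolerance = 1e-9)
  expect_lt(ultrametric_deviation(tr), 1e-8)

  # single species edge case
  tr1 <- simulate_species_tree(sim_config(n_species = 1, seed = 2))
  expect_equal(ape::Ntip(tr1), 1L)

  # radiation clade: all internal divergences below the radiation age
  set.seed(3)
  cfgr <- sim_config(n_species = 20, radiation = list(n_species = 10, age = 0.5),
                     seed = 3)
  trr <- simulate_species_tree(cfgr)
  rad <- attr(trr, "radiation_species")
  expect_equal(length(rad), 10L)
  expect_true(ape::is.monophyletic(trr, rad))
  node <- ape::getMRCA(trr, rad)
  expect_lt(node_heights(trr)[node], 0.5)
})

test_that("yule node counts grow at the expected exponential rate", {
  # for a crown-conditioned pure-birth tree the expected lineage count
  # at time t after the crown is 2 * exp(lambda * t); check the rescaled
  # simulator output against this with lambda implied by n and crown age
  set.seed(44)
  n <- 50; crown <- 20
  lam <- log(n / 2) / crown
  counts <- replicate(120, {
    cfg <- sim_config(n_species = n, crown_age = crown,
                      seed = sample.int(1e6, 1))
    tr <- simulate_species_tree(cfg)
    h <- node_heights(tr)[(n + 1):(2 * n - 1)]
    # lineages at 10 Ma after the crown (= height crown - 10)
    1 + sum(h > crown - 10)
  })
  expect_gt(mean(counts), 2 * exp(lam * 10) * 0.75)
  expect_lt(mean(counts), 2 * exp(lam * 10) * 1.35)
})

test_that("gene tree respects species boundaries and coalescent depth", {
  # one sample per species: gene tree mirrors the species tree topology
  cfg <- sim_config(n_species = 8, seed = 12, samples_mean = 1,
                    samples_max = 1, singleton_fraction = 1)
  set.seed(12)
  sp <- simulate_species_tree(cfg)
  gt <- simulate_gene_tree(sp, cfg)
  expect_equal(ape::Ntip(gt), 8L)
  map <- attr(gt, "specimen_species")
  relab <- gt
  relab$tip.label <- unname(map[gt$tip.label])
  expect_equal(suppressWarnings(ape::dist.topo(relab, sp)),
               structure(0, names = "PH85"), ignore_attr = TRUE)

  # coalescence never predates the species divergence constraint:
  # between-species pairs coalesce above the species MRCA height
  set.seed(13)
  cfg2 <- sim_config(n_species = 6, seed = 13)
  sp2 <- simulate_species_tree(cfg2)
  gt2 <- simulate_gene_tree(sp2, cfg2)
  map2 <- attr(gt2, "specimen_species")
  hg <- node_heights(gt2)
  hs <- node_heights(sp2)
  pairs <- utils::combn(ape::Ntip(gt2), 2)
  for (k in sample(ncol(pairs), 40)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    si <- map2[gt2$tip.label[i]]; sj <- map2[gt2$tip.label[j]]
    if (si == sj) next
    mrca_g <- hg[ape::getMRCA(gt2, c(i, j))]
    mrca_s <- hs[ape::getMRCA(sp2, match(c(si, sj), sp2$tip.label))]
    expect_gte(mrca_g, mrca_s - 1e-9)
  }
})

test_that("lineage sorting is complete when coalescence is shallow and
           incomplete inside a recent radiation", {
  mono_rate <- mean(sapply(1:30, function(s) {
    cfg <- recovery_config(300 + s, n_species = 10)
    set.seed(cfg$seed)
    sp <- simulate_species_tree(cfg)
    gt <- simulate_gene_tree(sp, cfg)
    all(species_monophyly(gt))
  }))
  expect_gte(mono_rate, 0.95)

  nonmono_rate <- mean(sapply(1:20, function(s) {
    d <- simulate_dataset(radiation_config(500 + s))
    mono <- species_monophyly(d$gene_tree)
    any(!mono[d$radiation_species])
  }))
  expect_gt(nonmono_rate, 0.5)
})

test_that("sequence divergence is calibrated to the pairwise rate", {
  # two tips whose ancestor sits 4.35 Ma back should differ by ~ 9%
  # (slightly under the 10% expectation, from multiple hits)
  cfg <- sim_config(n_species = 2, seed = 1)
  tree <- ape::read.tree(text = "(S0001:4.35,S0002:4.35);")
  attr(tree, "specimen_species") <- c(S0001 = "Gen a", S0002 = "Gen b")
  set.seed(77)
  p <- replicate(60, {
    aln <- evolve_sequences(tree, cfg)
    p_distance_matrix(aln)[1, 2]
  })
  expect_gt(mean(p), 0.080)
  expect_lt(mean(p), 0.100)

  # zero-length tree: identical sequences
  tree0 <- ape::read.tree(text = "(S0001:0,S0002:0);")
  attr(tree0, "specimen_species") <- c(S0001 = "Gen a", S0002 = "Gen b")
  aln0 <- evolve_sequences(tree0, cfg)
  expect_equal(aln0$sequence[1], aln0$sequence[2])
})

test_that("simulated alignments always pass the stop-codon screen", {
  for (s in 1:5) {
    d <- simulate_dataset(sim_config(n_species = 6, seed = 600 + s))
    expect_true(all(qc_translate(d$alignment)$pass))
  }
})

test_that("specimen sampling matches the configured distribution", {
  set.seed(55)
  cfg <- sim_config()
  sizes <- replicate(400, barcodiv:::draw_sample_sizes(1, cfg))
  expect_true(all(sizes >= 1 & sizes <= cfg$samples_max))
  expect_gt(mean(sizes == 1), 0.1)  # singleton inflation plus natural 1s
  expect_gt(mean(sizes), 3); expect_lt(mean(sizes), 7)
})

test_that("region assignment yields contiguous ranges and distance decay", {
  set.seed(66)
  cfg <- sim_config(n_species = 200, n_regions = 6)
  geo <- assign_regions(sprintf("Gen sp%03d", 1:200), cfg)
  # contiguous ranges
  idx <- split(as.integer(sub("R", "", geo$species_regions$region)),
               geo$species_regions$species)
  expect_true(all(vapply(idx, function(v) {
    all(diff(sort(v)) == 1)
  }, TRUE)))

  # species->region presence induces negative Sorensen distance decay
  neg <- mean(sapply(1:40, function(s) {
    set.seed(1000 + s)
    g <- assign_regions(sprintf("Gen sp%03d", 1:200), cfg)
    pres <- g$species_regions
    part <- new_partition(paste(pres$species, pres$region),
                          pres$species, kind = "morphospecies")
    rmap <- tibble::tibble(
      specimen_id = paste(pres$species, pres$region),
      region = pres$region
    )
    st <- sorensen(part, rmap)
    st <- dplyr::left_join(st, g$distances, by = c("region_a", "region_b"))
    distance_decay(st)$slope < 0
  }))
  expect_gte(neg, 0.95)

  # a single region is trivially identical to itself
  cfg1 <- sim_config(n_regions = 1)
  geo1 <- assign_regions("Gen sp001", cfg1)
  expect_equal(unique(geo1$species_regions$region), "R1")
})
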