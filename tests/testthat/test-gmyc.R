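test_that("preprocessing collapses identical haplotypes and fixes zero branches", {
  # two identical-haplotype tips (zero-height cherry) collapse to one
  tr <- ape::read.tree(text = "((a:0,b:0):1,(c:0.5,d:0.5):0.5);")
  pre <- preprocess_tree(tr)
  expect_equal(ape::Ntip(pre$tree), 3L)
  expect_equal(pre$aliases$alias, "b")
  expect_equal(pre$aliases$representative, "a")
  expect_true(all(pre$tree$edge.length > 0))

  # an already-clean tree is unchanged
  tr2 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  pre2 <- preprocess_tree(tr2)
  expect_equal(nrow(pre2$aliases), 0L)
  expect_equal(sort(node_heights(pre2$tree)), sort(node_heights(tr2)),
               tolerance = 1e-7)

  # polytomies are resolved, then perturbed into distinct positive heights
  tr3 <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  pre3 <- preprocess_tree(tr3)
  expect_true(ape::is.binary(pre3$tree))
  expect_true(all(pre3$tree$edge.length > 0))
})

test_that("entity re-expansion restores aliased haplotypes", {
  d <- simulate_dataset(recovery_config(41, n_species = 8))
  fit <- fit_gmyc(d$gene_tree)
  expect_setequal(fit$entities$specimen_id, d$alignment$specimen_id)
  if (nrow(fit$aliases)) {
    for (i in seq_len(nrow(fit$aliases))) {
      ga <- fit$entities$group[fit$entities$specimen_id == fit$aliases$alias[i]]
      gr <- fit$entities$group[
        fit$entities$specimen_id == fit$aliases$representative[i]]
      expect_equal(ga, gr)
    }
  }
})

test_that("mixed log-likelihood matches a hand-expanded sum on a 4-tip tree", {
  tree <- ape::read.tree(text = "((a:1,b:1):2,(c:1.5,d:1.5):1.5);")
  # heights: root 3, (a,b) at 1, (c,d) at 1.5; threshold at 2 ->
  # two coalescent groups of two tips each, one Yule event (the root)
  hand <- function(l1, p1, l2, p2) {
    yule <- log(l1 * 2^p1) - l1 * 2^p1 * (3 - 2) -  # root event + wait to T
      l1 * 2^p1 * 2                                 # 2 entities persist below T
    coal <- log(l2 * (2^p2 + 2^p2)) - l2 * (2^p2 + 2^p2) * 1 +  # (a,b) at 1
      log(l2 * 2^p2) - l2 * 2^p2 * 0.5 +                        # (c,d) at 1.5
      0                                             # (1.5, 2): no pairs left
    yule + coal
  }
  for (pars in list(c(1, 1, 1, 1), c(0.3, 1.7, 2.5, 0.4), c(2, 0, 0.1, 2.2))) {
    expect_equal(
      gmyc_loglik(tree, 2, pars[1], pars[2], pars[3], pars[4]),
      hand(pars[1], pars[2], pars[3], pars[4]),
      tolerance = 1e-10
    )
  }
})

test_that("threshold limits recover the single-process likelihoods", {
  set.seed(71)
  tr <- ape::rcoal(15)
  H <- max(node_heights(tr))

  # T at the root: pure single-group coalescent (the persisting single
  # entity adds the -lambda1 * H survival term)
  for (pars in list(c(1e-8, 1, 2, 1), c(1e-8, 0.5, 0.7, 1.8))) {
    expect_equal(
      gmyc_loglik(tr, H * (1 + 1e-9), pars[1], pars[2], pars[3], pars[4]),
      oracle_pure_coal(tr, pars[3], pars[4]) - pars[1] * 1^pars[2] * H * (1 + 1e-9),
      tolerance = 1e-8
    )
  }

  # T = 0: pure diversification over the whole tree
  for (pars in list(c(1.2, 1, 5, 1), c(0.4, 2.1, 1, 0))) {
    expect_equal(
      gmyc_loglik(tr, 0, pars[1], pars[2], pars[3], pars[4]),
      oracle_pure_yule(tr, pars[1], pars[2]),
      tolerance = 1e-10
    )
  }

  # invalid parameter points are rejected
  expect_error(gmyc_loglik(tr, 0.1, -1, 1, 1, 1), "rates")
  expect_error(gmyc_loglik(tr, -0.1, 1, 1, 1, 1), "T must")
})

test_that("fitted threshold is the profile maximum and beats the null", {
  d <- simulate_dataset(recovery_config(42, n_species = 10))
  fit <- fit_gmyc(d$gene_tree)
  expect_true(all(fit$profile$loglik <= fit$logL_model + 1e-9))
  expect_gte(fit$logL_model, fit$logL_null - 1e-6)
  expect_true(fit$T_hat %in% fit$ci_thresholds)
  expect_gte(fit$n_entities, 1L)
  expect_lte(fit$n_entities, fit$n_tips)

  # entities are connected below-threshold subtrees: every entity is
  # monophyletic on the reduced tree
  tr <- fit$tree
  groups <- split(fit$entities$specimen_id, fit$entities$group)
  groups <- lapply(groups, intersect, tr$tip.label)
  for (g in groups) {
    if (length(g) >= 2) expect_true(ape::is.monophyletic(tr, g))
  }

  # glance/tidy interface
  gl <- glance(fit)
  expect_equal(gl$n_entities, fit$n_entities)
  td <- tidy(fit)
  expect_setequal(td$specimen_id, d$alignment$specimen_id)
})

test_that("gmyc recovers well-separated species and its accuracy bounds hold", {
  hits <- sapply(1:10, function(s) {
    d <- simulate_dataset(recovery_config(700 + s, n_species = 12))
    fit <- fit_gmyc(d$gene_tree)
    ev <- evaluate_partition(fit$entities, d$truth)
    expect_lte(ev$accuracy_pct, ev$agreement_pct + 1e-9)
    abs(fit$n_entities - 12) / 12 <= 0.1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("non-monophyletic radiation species are lumped by gmyc as by clustering", {
  d <- simulate_dataset(radiation_config(800))
  fit <- fit_gmyc(d$gene_tree)
  evg <- evaluate_partition(fit$entities, d$truth)
  dm <- p_distance_matrix(d$alignment)
  evc <- evaluate_partition(cluster_at_threshold(dm, 0.03), d$truth)
  expect_lt(evg$accuracy_pct, 100)
  expect_lt(evc$accuracy_pct, 100)
  expect_gte(evg$n_groups_lumped, 1L)
  expect_gte(evc$n_groups_lumped, 1L)
})
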