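# A fixed 5-tip ultrametric tree with printed node times, used for the
# hand-summed likelihood checks: node ages 10 (root), 6, 3, 1.
fixture_tree <- function() {
  ape::read.tree(text = paste0(
    "((a:6,(b:3,(c:1,d:1):2):3):4,e:10);"
  ))
}

test_that("threshold extremes reduce to pure Yule and pure coalescent", {
  tr <- fixture_tree()
  ly <- 0.23
  lc <- 7.7
  # threshold younger than every node: every tip its own cluster, no
  # coalescent intervals remain
  ll_yule <- gmyc_loglik(tr, 0.5, ly, lc)
  # hand-summed pure Yule: intervals (6,10],(3,6],(1,3] with 2,3,4 lineages
  hand <- (log(2 * ly) - 2 * ly * 4) + (log(3 * ly) - 3 * ly * 3) +
    (log(4 * ly) - 4 * ly * 2)
  expect_equal(ll_yule, hand, tolerance = 1e-12)
  expect_equal(ll_yule, gmyc_loglik(tr, 0, ly, lc), tolerance = 1e-12)
  # threshold at the root: single coalescent over the whole tree;
  # bands carry 2, 3, 4 lineages -> n(n-1) = 2, 6, 12
  ll_null <- gmyc_loglik(tr, 10, ly, lc)
  hand_null <- (log(lc * 2) - lc * 2 * 4) +
    (log(lc * 6) - lc * 6 * 3) + (log(lc * 12) - lc * 12 * 2)
  expect_equal(ll_null, hand_null, tolerance = 1e-12)
  # rate_yule is irrelevant in the degenerate single-coalescent model
  expect_equal(ll_null, gmyc_loglik(tr, 11, 99, lc), tolerance = 1e-12)
})

test_that("a mixed threshold matches the hand-summed waiting-time density", {
  tr <- fixture_tree()
  ly <- 0.4
  lc <- 2.5
  # threshold at age 4.5: nodes at 10, 6 are Yule; 3, 1 coalescent.
  # crossing lineages: a, e, and the (b,(c,d)) ancestor -> 3 "species"
  # lineages (cluster sizes 1, 1, 3); the Yule count stays 3 below the
  # threshold. Intervals: (6,10] pure Yule with 2 lineages; (3,6] rate
  # 3*ly (the one multi-tip cluster still has a single lineage, so its
  # Kingman term is zero); (1,3] the (b,(c,d)) cluster has 2 lineages.
  hand <- (log(2 * ly) - 2 * ly * 4) +
    (log(3 * ly) - 3 * ly * 3) +
    (log(3 * ly + lc * 2) - (3 * ly + lc * 2) * 2)
  expect_equal(gmyc_loglik(tr, 4.5, ly, lc), hand, tolerance = 1e-12)
})

test_that("non-ultrametric or tiny trees are rejected", {
  expect_error(gmyc_loglik(ape::rtree(6), 0.5, 1, 1),
    class = "mitodiv_format_error")
  expect_error(fit_gmyc(simulate_coalescent_genealogy(3, 0.02, seed = 1)),
    class = "mitodiv_insufficient_data")
})

test_that("a comb-like single coalescent does not split into clusters", {
  # perfectly comb-shaped tree: no threshold yields a second multi-tip
  # cluster, and the mixed model is never significantly preferred
  tr <- ape::read.tree(
    text = "(((a:1,b:1):2,c:3):3,d:6);"
  )
  fit <- fit_gmyc(tr)
  expect_equal(fit$n_clusters, 1L)
  expect_gt(fit$p, 0.05)
})

test_that("largest_cluster prefers multi-tip clusters and breaks ties", {
  mk <- function(sizes, tips, clusters) {
    structure(list(
      cluster_sizes = sizes,
      cluster_assignments = tibble::tibble(
        tip = tips, cluster = clusters,
        singleton = sizes[clusters] < 2L
      )
    ), class = "gmyc_fit")
  }
  # {6,3,2}: the 6-tip cluster wins
  f <- mk(c(6L, 3L, 2L), sprintf("t%02d", 1:11),
    rep(1:3, c(6, 3, 2)))
  expect_equal(largest_cluster(f), sprintf("t%02d", 1:6))
  # tie {3,3}: the cluster holding the alphabetically first tip
  f2 <- mk(c(3L, 3L), c("m1", "m2", "m3", "a1", "a2", "a3"),
    rep(1:2, each = 3))
  expect_equal(largest_cluster(f2), c("a1", "a2", "a3"))
  # singletons only eligible when no multi-tip cluster exists
  f3 <- mk(c(1L, 4L, 1L), c("a", paste0("b", 1:4), "c"),
    c(1L, rep(2L, 4), 3L))
  expect_equal(largest_cluster(f3), paste0("b", 1:4))
})

test_that("two well-separated clusters are recovered", {
  g1 <- simulate_coalescent_genealogy(6, 0.02, seed = 31,
    tip_labels = paste0("a", 1:6))
  g2 <- simulate_coalescent_genealogy(5, 0.02, seed = 32,
    tip_labels = paste0("b", 1:5))
  tr <- mitodiv:::bind_at_age(g1, g2, 50 * 0.01)
  fit <- fit_gmyc(tr, tree_id = "pair")
  expect_equal(fit$n_clusters, 2L)
  expect_lt(fit$p, 0.05)
  expect_equal(largest_cluster(fit), paste0("a", 1:6))
  # assignments partition the tips
  asn <- fit$cluster_assignments
  expect_setequal(asn$tip, tr$tip.label)
  expect_false(any(is.na(asn$cluster)))
  # the fitted mixed model beats the null and the LRT is its doubled gap
  expect_equal(fit$lrt_stat,
    2 * (fit$loglik_mixed - fit$loglik_null))
  expect_gte(fit$lrt_stat, 0)
})

test_that("cluster-count ties break to the alphabetically first tip", {
  g1 <- simulate_coalescent_genealogy(4, 0.02, seed = 33,
    tip_labels = c("z1", "z2", "z3", "z4"))
  g2 <- simulate_coalescent_genealogy(4, 0.02, seed = 34,
    tip_labels = c("a1", "a2", "a3", "a4"))
  tr <- mitodiv:::bind_at_age(g1, g2, 2)
  fit <- fit_gmyc(tr)
  if (fit$n_clusters == 2L) {
    expect_equal(largest_cluster(fit), paste0("a", 1:4))
  } else {
    succeed("fit collapsed to a single cluster on this fixture")
  }
})

test_that("cluster recovery improves with the depth separation", {
  # the pipeline's readout: the ML cluster count when the mixed model is
  # significantly preferred, one panmictic cluster otherwise
  set.seed(35)
  acc <- sapply(c(2, 10, 50), function(ratio) {
    mean(replicate(15, {
      f <- fit_gmyc(make_two_scale_tree(4, 5, 0.02, ratio))
      k <- if (f$p < 0.05) f$n_clusters else 1L
      k == 4L
    }))
  })
  expect_true(all(diff(acc) >= 0))
  expect_lt(acc[1], 0.4)
  expect_gt(acc[3], 0.6)
})

test_that("re-estimation on a subset reproduces and bounds diversity", {
  set.seed(36)
  g1 <- simulate_coalescent_genealogy(5, 0.02,
    tip_labels = paste0("a", 1:5))
  g2 <- simulate_coalescent_genealogy(4, 0.02,
    tip_labels = paste0("b", 1:4))
  tr <- mitodiv:::bind_at_age(g1, g2, 0.5)
  aln <- simulate_codon_sequences(tr, 300, mu = 1,
    neutral_nonsyn_fraction = 0.1, species_id = "sp")
  full <- pairwise_pi(aln)
  # keeping everyone reproduces the original estimate
  all_ids <- names(aln$sequences)
  expect_equal(reestimate_diversity(aln, all_ids), full)
  # dropping the divergent cluster cannot increase piS on this fixture
  sub <- reestimate_diversity(aln, paste0("a", 1:5))
  expect_lte(sub$pi_s, full$pi_s)
  # two identical sequences give exactly zero diversity
  aln2 <- species_alignment("sp", c(x = "ATGTTT", y = "ATGTTT",
    z = "ATGTTC"))
  expect_equal(reestimate_diversity(aln2, c("x", "y"))$pi_s, 0)
  expect_error(reestimate_diversity(aln2, "x"),
    class = "mitodiv_insufficient_data")
  expect_error(reestimate_diversity(aln2, c("x", "nope")),
    class = "mitodiv_format_error")
})
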