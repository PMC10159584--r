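test_that("Yule trees are ultrametric, sized and reproducible", {
  tr <- simulate_yule_tree(10, 1, seed = 1)
  expect_equal(ape::Ntip(tr), 10L)
  expect_true(is_ultrametric(tr))
  expect_true(ape::is.binary(tr))
  tr2 <- simulate_yule_tree(10, 1, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_false(identical(
    ape::write.tree(simulate_yule_tree(10, 1, seed = 2)),
    ape::write.tree(tr)
  ))
})

test_that("Yule root age shrinks with the birth rate", {
  set.seed(2)
  depth <- function(b) {
    mean(replicate(150, {
      max(ape::node.depth.edgelength(simulate_yule_tree(8, b)))
    }))
  }
  d1 <- depth(1)
  d4 <- depth(4)
  # expected depth scales as 1/birth rate
  expect_gt(d1 / d4, 2.5)
  expect_lt(d1 / d4, 6)
})

test_that("coalescent genealogies hit the closed-form expectations", {
  set.seed(3)
  # n = 2: height ~ Exp(1) in coalescent units, scaled by theta/2
  h <- replicate(2000, {
    max(ape::node.depth.edgelength(simulate_coalescent_genealogy(2, 0.02)))
  })
  expect_equal(mean(h), 0.01, tolerance = 0.05)
  # random-pair path length averages theta for larger samples
  set.seed(4)
  paths <- replicate(300, {
    g <- simulate_coalescent_genealogy(6, 0.02)
    d <- ape::cophenetic.phylo(g)
    mean(d[upper.tri(d)])
  })
  expect_equal(mean(paths), 0.02, tolerance = 0.05)
  g1 <- simulate_coalescent_genealogy(5, 0.02, seed = 9)
  g2 <- simulate_coalescent_genealogy(5, 0.02, seed = 9)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
})

test_that("sequence simulation respects its degenerate limits", {
  g <- simulate_coalescent_genealogy(5, 0.05, seed = 5)
  a0 <- simulate_codon_sequences(g, 50, mu = 0, seed = 6)
  expect_equal(length(unique(a0$sequences)), 1L)
  est0 <- pairwise_pi(a0)
  expect_equal(est0$pi_s, 0)
  expect_equal(est0$pi_n, 0)
  # no neutral nonsynonymous mutations: piN stays at zero
  a1 <- simulate_codon_sequences(g, 200, mu = 1,
    neutral_nonsyn_fraction = 0, seed = 7)
  expect_equal(pairwise_pi(a1)$pi_n, 0)
  # determinism
  a2 <- simulate_codon_sequences(g, 200, mu = 1,
    neutral_nonsyn_fraction = 0, seed = 7)
  expect_identical(a1$sequences, a2$sequences)
  # alignments stay in frame: no internal stops at the root sequence level
  tb <- genetic_code()
  cods <- substring(a1$sequences[1], seq(1, 598, 3), seq(3, 600, 3))
  expect_false(any(tb[cods] == "*"))
})

test_that("piS tracks the calibrated per-synonymous-site target", {
  set.seed(8)
  kappa <- ng86_calibration()[["kappa_s"]]
  pis <- replicate(60, {
    g <- simulate_coalescent_genealogy(6, 0.02)
    pairwise_pi(simulate_codon_sequences(g, 300, mu = kappa,
      neutral_nonsyn_fraction = 0))$pi_s
  })
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.02), 3 * se)
})

test_that("piN/piS is governed by the neutral fraction", {
  set.seed(9)
  kappa <- ng86_calibration()
  est <- purrr::map_dfr(1:40, function(i) {
    g <- simulate_coalescent_genealogy(8, 0.05)
    pairwise_pi(simulate_codon_sequences(g, 300, mu = kappa[["kappa_s"]],
      neutral_nonsyn_fraction = 0.2))
  })
  ratio <- sum(est$pi_n) / sum(est$pi_s)
  expect_equal(ratio, 0.2, tolerance = 0.25)
})

test_that("trait simulation is exact in its noiseless limit", {
  tr <- simulate_yule_tree(40, 1, seed = 10)
  tt <- simulate_traits(tr, 1,
    base_traits = list(range_km2 = list(mean = 5, sd = 1)),
    slope_structure = list(
      pis = list(partner = "range_km2", slope = 0.2, noise_sd = 0,
        mean = -2)
    ), seed = 11)
  cx <- compute_contrasts(setNames(log10(tt$range_km2), tt$species_id), tr)
  cy <- compute_contrasts(setNames(log10(tt$pis), tt$species_id), tr)
  expect_equal(origin_correlation(cx, cy)$r, 1, tolerance = 1e-8)
  fit <- origin_regression(cy, cx)
  expect_equal(unname(fit$slopes), 0.2, tolerance = 1e-8)
  # lambda = 1 simulation recovers a high lambda
  lf <- fit_lambda(setNames(log10(tt$range_km2), tt$species_id), tr)
  expect_gt(lf$lambda_hat, 0.7)
})

test_that("a generated study is complete, faithful and reproducible", {
  cfg <- synthetic_config(
    n_species = 25L, ind_range = c(2L, 30L), n_codons = 120L,
    substructure_fraction = 0.2, seed = 42L
  )
  dir1 <- withr::local_tempdir()
  truth <- make_study(cfg, dir1)
  expect_length(list.files(file.path(dir1, "alignments")), 25L)
  expect_length(list.files(file.path(dir1, "gene_trees")), 25L)
  expect_true(file.exists(file.path(dir1, "species_tree.nwk")))
  expect_true(file.exists(file.path(dir1, "traits.csv")))
  # truth round trip
  tj <- jsonlite::read_json(file.path(dir1, "truth.json"))
  expect_equal(tj$seed, 42L)
  expect_equal(tj$slope_pis_range, cfg$slope_pis_range)
  expect_equal(length(tj$theta_s), 25L)
  expect_equal(unlist(tj$n_clusters)[unlist(tj$substructured_species)],
    setNames(rep(2L, length(tj$substructured_species)),
      unlist(tj$substructured_species)))
  # exactly ceil(0.2 x 25) = 5 species flagged
  expect_length(tj$substructured_species, 5L)
  # sample sizes within the configured bounds; gene trees match alignments
  sizes <- unlist(tj$individuals)
  expect_true(all(sizes >= 2 & sizes <= 30))
  one <- read_alignment(file.path(dir1, "alignments", "sp001.fasta"))
  gt <- read_tree(file.path(dir1, "gene_trees", "sp001.nwk"))
  expect_setequal(names(one$sequences), gt$tip.label)
  # determinism: regenerating gives identical files
  dir2 <- withr::local_tempdir()
  make_study(cfg, dir2)
  f1 <- readLines(file.path(dir1, "alignments", "sp007.fasta"))
  f2 <- readLines(file.path(dir2, "alignments", "sp007.fasta"))
  expect_identical(f1, f2)
  expect_identical(
    readLines(file.path(dir1, "species_tree.nwk")),
    readLines(file.path(dir2, "species_tree.nwk"))
  )
})

test_that("generated studies assemble with high retention", {
  cfg <- synthetic_config(
    n_species = 60L, ind_range = c(2L, 60L), seed = 7L
  )
  dir <- withr::local_tempdir()
  make_study(cfg, dir)
  div <- diversity_table(file.path(dir, "alignments"))
  ds <- assemble_dataset(
    div, read_trait_table(file.path(dir, "traits.csv")),
    read_tree(file.path(dir, "species_tree.nwk"))
  )
  expect_gte(nrow(ds$data) / 60, 0.9)
  # median individuals lands near the configured target
  expect_gt(median(ds$data$n_individuals), 10)
  expect_lt(median(ds$data$n_individuals), 45)
})
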