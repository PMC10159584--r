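test_that("the BM likelihood degenerates correctly at lambda extremes", {
  tr <- simulate_yule_tree(12, 1, seed = 2)
  x <- setNames(rnorm(12), tr$tip.label)
  # lambda = 0: independent normals with per-tip depth variance
  V <- ape::vcv(tr)
  depths <- diag(V)
  ll0 <- bm_loglik(x, tr, 0)
  mu <- sum(x[rownames(V)] / depths) / sum(1 / depths)
  s2 <- sum((x[rownames(V)] - mu)^2 / depths) / 12
  ll_direct <- sum(stats::dnorm(x[rownames(V)], mu, sqrt(s2 * depths),
    log = TRUE))
  expect_equal(ll0, ll_direct, tolerance = 1e-10)
  # ultrametric star tree: off-diagonals are zero, lambda is irrelevant
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  star <- ape::multi2di(star, random = FALSE)
  star$edge.length[star$edge.length == 0] <- 1e-12
  xs <- setNames(rnorm(5), letters[1:5])
  expect_equal(bm_loglik(xs, star, 0), bm_loglik(xs, star, 1),
    tolerance = 1e-6)
})

test_that("the BM likelihood matches a direct MVN oracle on small trees", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    V <- ape::vcv(tr)
    for (lam in c(0, 0.3, 0.7, 1)) {
      expect_equal(bm_loglik(x, tr, lam),
        oracle_bm_loglik(x[rownames(V)], V, lam),
        tolerance = 1e-8)
    }
  }
})

test_that("lambda fitting separates strong signal from none", {
  tr <- simulate_yule_tree(80, 1, seed = 11)
  bm <- simulate_traits(tr, 1, base_traits = list(z = list(mean = 0, sd = 1)),
    seed = 3)
  v <- setNames(log10(bm$z), bm$species_id)
  fit1 <- fit_lambda(v, tr, trait_name = "bm")
  expect_gt(fit1$lambda_hat, 0.8)
  expect_lt(fit1$p_lrt, 0.01)
  expect_equal(fit1$lrt_stat,
    2 * (fit1$loglik_hat - fit1$loglik_lambda0))
  set.seed(4)
  iid <- setNames(rnorm(80), tr$tip.label)
  fit0 <- fit_lambda(iid, tr, trait_name = "iid")
  expect_lt(fit0$lambda_hat, 0.3)
})

test_that("permutation p-values respect their attainable floor", {
  tr <- simulate_yule_tree(40, 1, seed = 12)
  bm <- simulate_traits(tr, 1, base_traits = list(z = list(mean = 0, sd = 1)),
    seed = 5)
  v <- setNames(log10(bm$z), bm$species_id)
  fit <- fit_lambda(v, tr, n_perm = 19, seed = 9)
  expect_equal(fit$p_perm, 1 / 20) # strong signal beats every shuffle
  expect_gte(fit$p_perm, 1 / (1 + 19))
})

test_that("contrasts reproduce the hand-run pruning recursion", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  # a cherry: contrast (3 - 1)/sqrt(2)
  expect_error(compute_contrasts(setNames(c(3, 1), c("A", "B")), tr),
    class = "mitodiv_insufficient_data")
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  ct <- compute_contrasts(setNames(c(3, 1, 2), c("A", "B", "C")), tr2)
  expect_setequal(round(ct$contrast, 10), round(c(2 / sqrt(2), 0), 10))
  # n - 1 contrasts on random binary trees; matches hand recursion
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    ct <- compute_contrasts(x, tr)
    expect_equal(nrow(ct), n - 1)
    expect_setequal(round(abs(ct$contrast), 8),
      round(abs(oracle_pic(x, tr)), 8))
  }
})

test_that("origin correlation handles exact proportionality and sign flips", {
  x <- tibble::tibble(node = 1:6, contrast = c(1, -2, 3, 0.5, -1, 2))
  y2 <- dplyr::mutate(x, contrast = 2 * contrast)
  expect_equal(origin_correlation(x, y2)$r, 1)
  yneg <- dplyr::mutate(x, contrast = -contrast)
  expect_equal(origin_correlation(x, yneg)$r, -1)
  # joint sign flips leave r unchanged
  set.seed(8)
  yr <- dplyr::mutate(x, contrast = rnorm(6))
  r1 <- origin_correlation(x, yr)$r
  flip <- c(1, -1, 1, -1, -1, 1)
  xf <- dplyr::mutate(x, contrast = contrast * flip)
  yf <- dplyr::mutate(yr, contrast = contrast * flip)
  expect_equal(origin_correlation(xf, yf)$r, r1, tolerance = 1e-12)
  expect_error(origin_correlation(x, dplyr::mutate(x, contrast = 0)),
    class = "mitodiv_degenerate")
})

test_that("origin correlation equals GLS correlation via contrasts", {
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(rnorm(n), tr$tip.label)
    cx <- compute_contrasts(x, tr)
    cy <- compute_contrasts(y, tr)
    r <- origin_correlation(cx, cy)$r
    V <- ape::vcv(tr)
    expect_equal(r, oracle_gls_corr(x[rownames(V)], y[rownames(V)], V),
      tolerance = 1e-8)
  }
})

test_that("origin regression is exact on noiseless and orthogonal cases", {
  x <- tibble::tibble(node = 1:8, contrast = c(1, -2, 3, 0.5, -1, 2, 4, -3))
  y <- dplyr::mutate(x, contrast = 0.2 * contrast)
  fit <- origin_regression(y, x)
  expect_equal(fit$slopes, 0.2, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0, tolerance = 1e-10)
  # orthogonal predictors: multiple slopes equal their marginal values
  x1 <- tibble::tibble(node = 1:4, contrast = c(1, 1, -1, -1))
  x2 <- tibble::tibble(node = 1:4, contrast = c(1, -1, 1, -1))
  yy <- tibble::tibble(node = 1:4, contrast = 3 * x1$contrast -
    2 * x2$contrast + c(0.1, -0.1, 0.05, -0.05))
  fit2 <- origin_regression(yy, list(a = x1, b = x2))
  m1 <- origin_regression(yy, x1)$slopes
  m2 <- origin_regression(yy, x2)$slopes
  expect_equal(unname(fit2$slopes), c(m1, m2), tolerance = 1e-10)
  # r^2 of single-predictor origin regression equals r^2 of the correlation
  set.seed(10)
  yr <- dplyr::mutate(x, contrast = 0.3 * x$contrast + rnorm(8))
  expect_equal(origin_regression(yr, x)$r_squared,
    origin_correlation(x, yr)$r^2,
    tolerance = 1e-10)
  expect_error(origin_regression(yy, list(x1, x1)),
    class = "mitodiv_degenerate")
})

test_that("percent change per doubling is exact and monotone", {
  expect_equal(percent_change_per_doubling(0), 0)
  expect_equal(percent_change_per_doubling(1), 100)
  expect_equal(round(percent_change_per_doubling(0.20)), 15)
  b <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(percent_change_per_doubling(b)) > 0))
})

test_that("pairwise deletion gives each trait pair its own n", {
  tr <- simulate_yule_tree(30, 1, seed = 21)
  traits <- simulate_traits(tr, 1,
    base_traits = list(
      range_km2 = list(mean = 5, sd = 1),
      mass_g = list(mean = 2, sd = 0.5)
    ), seed = 22)
  ids <- traits$species_id
  div <- tibble::tibble(
    species_id = ids, n_individuals = 10L,
    pi_s = 10^rnorm(30, -2, 0.3), pi_n = 10^rnorm(30, -3, 0.3),
    ratio = NA_real_, syn_sites_total = 100, nonsyn_sites_total = 300,
    n_pairs = 45L
  )
  div$ratio <- div$pi_n / div$pi_s
  traits$mass_g[1:12] <- NA
  ds <- assemble_dataset(div, traits, tr)
  tab <- contrast_correlations(ds,
    predictors = c("log_range_km2", "log_mass_g"))
  n_range <- tab$n[tab$predictor == "log_range_km2"][1]
  n_mass <- tab$n[tab$predictor == "log_mass_g"][1]
  expect_equal(n_range, 29L)
  expect_equal(n_mass, 17L) # 18 species with mass -> 17 contrasts
})
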