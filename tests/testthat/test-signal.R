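test_that("K equals 1 identically on an equal-branch star tree", {
  st <- star_tree(12)
  set.seed(1)
  ks <- vapply(1:50, function(i) {
    x <- stats::setNames(stats::rnorm(12), st$tip.label)
    blomberg_k(st, x, n_rand = 0)$estimate
  }, numeric(1))
  expect_equal(ks, rep(1, 50), tolerance = 1e-10)
})

test_that("K agrees with the reference implementation and fixed seeds", {
  tr <- yule_tree(50, seed = 30)
  x <- simulate_continuous_traits(tr, sig2 = 2, lambda = 1, seed = 31)
  k1 <- blomberg_k(tr, x, n_rand = 200, seed = 7)
  k2 <- blomberg_k(tr, x, n_rand = 200, seed = 7)
  expect_identical(k1$p_value, k2$p_value)
  ref <- phytools::phylosig(tr, x, method = "K")
  expect_equal(k1$estimate, unname(as.numeric(ref)), tolerance = 1e-6)
})

test_that("continuous lambda hits its closed-form endpoints", {
  tr <- yule_tree(40, seed = 33)
  x <- simulate_continuous_traits(tr, sig2 = 1, lambda = 1, seed = 34)
  res <- pagel_lambda_continuous(tr, x)
  # lnL at the estimate dominates both endpoints
  C <- ape::vcv.phylo(tr)
  ll1 <- traitsse:::bm_profile(chol(C), x[tr$tip.label])$loglik
  n <- 40
  depth <- max(node_depths(tr)[1:n])
  xo <- x[tr$tip.label]
  s2 <- mean((xo - mean(xo))^2)
  ll0 <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_gte(res$loglik, ll1 - 1e-8)
  expect_gte(res$loglik, ll0 - 1e-8)
  expect_equal(res$loglik_null, ll0, tolerance = 1e-8)

  # the reference optimizes lambda on a slightly wider interval; clamp to
  # the [0, 1] domain used here
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(res$estimate, min(ref$lambda, 1), tolerance = 1e-3)
})

test_that("lambda = 0.5 is recovered from simulated data", {
  lams <- vapply(1:20, function(i) {
    tr <- yule_tree(256, seed = 400 + i)
    x <- simulate_continuous_traits(tr, sig2 = 1, lambda = 0.5,
                                    seed = 500 + i)
    pagel_lambda_continuous(tr, x)$estimate
  }, numeric(1))
  expect_gte(stats::median(lams), 0.3)
  expect_lte(stats::median(lams), 0.7)
})

test_that("K and lambda are invariant to affine transforms", {
  tr <- yule_tree(36, seed = 40)
  x <- simulate_continuous_traits(tr, lambda = 0.7, seed = 41)
  k0 <- blomberg_k(tr, x, n_rand = 0)$estimate
  l0 <- pagel_lambda_continuous(tr, x)$estimate
  y <- 3.2 - 1.7 * x
  expect_equal(blomberg_k(tr, y, n_rand = 0)$estimate, k0, tolerance = 1e-8)
  expect_equal(pagel_lambda_continuous(tr, y)$estimate, l0,
               tolerance = 1e-5)
})

test_that("the discrete-lambda transform collapses correctly at 0 and 1", {
  tr <- yule_tree(20, seed = 50)
  spec <- build_rate_matrix(sml_alphabet, "ER", root = "uniform")
  sim <- simulate_mk_traits(tr, spec, 0.5, seed = 51)
  t1 <- lambda_transform_tree(tr, 1)
  expect_equal(t1$edge.length, tr$edge.length, tolerance = 1e-12)
  t0 <- lambda_transform_tree(tr, 0)
  d <- node_depths(t0)
  # all internal branches vanish: every tip hangs from the root at full depth
  expect_equal(unname(d[1:20]), rep(max(d[1:20]), 20), tolerance = 1e-9)
  expect_equal(mk_loglik(t1, sim$tip_states, spec, 0.5),
               mk_loglik(tr, sim$tip_states, spec, 0.5), tolerance = 1e-10)
})

test_that("discrete lambda detects strong phylogenetic signal", {
  hits <- vapply(1:8, function(i) {
    tr <- yule_tree(64, seed = 600 + i)
    depth <- max(node_depths(tr)[1:64])
    spec <- build_rate_matrix(sml_alphabet, "ER", root = "uniform")
    rate <- 1.5 / depth  # roughly 1-2 expected changes per lineage path
    sim <- simulate_mk_traits(tr, spec, rate, seed = 700 + i)
    if (length(unique(sim$tip_states)) < 2) return(NA_real_)
    pagel_lambda_discrete(tr, sim$tip_states, spec, n_starts = 2,
                          seed = 1)$estimate
  }, numeric(1))
  expect_gte(sum(hits > 0.8, na.rm = TRUE), 5)
})

test_that("phylogenetic ANOVA reproduces the direct F and extreme cases", {
  tr <- yule_tree(30, seed = 60)
  set.seed(61)
  groups <- stats::setNames(sample(c("g1", "g2", "g3"), 30, replace = TRUE),
                            tr$tip.label)
  y <- simulate_continuous_traits(tr, seed = 62)
  res <- phyl_anova(tr, groups, y, n_sim = 100, seed = 63)
  expect_equal(res$F, oracle_anova_F(groups[tr$tip.label], y[tr$tip.label]),
               tolerance = 1e-10)

  # huge group separation on a star tree: p at the resolution floor
  st <- star_tree(20)
  g2 <- stats::setNames(rep(c("a", "b"), each = 10), st$tip.label)
  y2 <- stats::setNames(rep(c(0, 100), each = 10) +
                          stats::rnorm(20, sd = 1e-3), st$tip.label)
  res2 <- phyl_anova(st, g2, y2, n_sim = 2000, seed = 64)
  expect_lte(res2$p_value, 0.001)

  expect_error(phyl_anova(tr, stats::setNames(rep("a", 30), tr$tip.label),
                          y), "2 groups")
})
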