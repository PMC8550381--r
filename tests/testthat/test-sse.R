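test_that("the eight-model set has the documented structure", {
  set <- build_model_set("size")
  expect_length(set, 8)
  expect_setequal(names(set),
                  c("Dull", "MuSSE", "MuHiSSE", "MuHiSSE Relaxed",
                    "Large Absorbing", "Small Absorbing", "CID2", "CID3"))
  k <- vapply(set, `[[`, numeric(1), "n_free")
  # the equal-rates null is the smallest model of the set
  expect_true(all(k["Dull"] < k[setdiff(names(k), "Dull")]))
  # relaxing the hidden transition adds exactly one parameter
  expect_equal(unname(k["MuHiSSE Relaxed"] - k["MuHiSSE"]), 1)
  # one extra hidden class costs one turnover + one extinction fraction
  expect_equal(unname(k["CID3"] - k["CID2"]), 2)

  # constrained mask: extremes never interconvert directly, in any model
  for (sp in set) {
    obs <- sp$comp_obs
    direct <- sp$q_map[obs == "01", obs == "10", drop = FALSE]
    expect_true(all(direct == 0))
    expect_true(all(sp$q_map[obs == "10", obs == "01"] == 0))
  }
  # absorbing structure: no observed moves out of the absorbing state
  la <- set[["Large Absorbing"]]
  expect_true(all(la$q_map[la$comp_obs == "10", la$comp_obs == "11"] == 0))
  # but hidden-class moves within the absorbing state remain possible
  idx10 <- which(la$comp_obs == "10")
  expect_true(any(la$q_map[idx10, idx10] > 0))
  # CID models tie diversification to hidden classes only
  cid <- set[["CID2"]]
  expect_equal(cid$tau_map, rep(1:2, each = 3))

  expect_error(build_model_set("shape"), "arg")
})

test_that("turnover/extinction-fraction reparameterization is exact", {
  set <- build_model_set("size")
  sp <- set$MuSSE
  par <- c(0.5, 0.8, 0.3, 0.2, 0.6, 0.1, 0.05, 0.04, 0.03, 0.02)
  p <- traitsse:::sse_expand(sp, par)
  expect_equal(p$lambda + p$mu, p$tau, tolerance = 1e-12)
  expect_equal(p$mu / p$lambda, p$eps, tolerance = 1e-12)
})

test_that("single-state SSE reduces to the Yule closed form", {
  tr <- read_tree("(((A:1,B:1):1,(C:1,D:1):1):1,E:3);")
  spec <- sse_spec("yule", obs_states = "01", hidden = 1, tau_map = 1L,
                   eps_map = 1L, q_map = matrix(0L, 1, 1),
                   rho = c("01" = 1), root = "uniform")
  tips <- stats::setNames(rep("01", 5), c("A", "B", "C", "D", "E"))
  for (lam in c(0.15, 0.4, 0.9)) {
    ll <- sse_loglik(tr, tips, spec,
                     list(lambda = lam, mu = 0, Q = matrix(0, 1, 1)))
    expect_equal(ll, (5 - 2) * log(lam) - lam * sum(tr$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("state-independent diversification factorizes into BD x Mk", {
  tr <- tree6()
  spec <- sse_spec("fact", hidden = 1, tau_map = rep(1L, 3),
                   eps_map = rep(1L, 3),
                   q_map = traitsse:::sse_default_qmap(c("01", "10", "11"), 1),
                   rho = c("01" = 1, "10" = 1, "11" = 1), root = "uniform")
  tips <- stats::setNames(c("01", "11", "10", "11", "01", "11"),
                          LETTERS[1:6])
  lam <- 0.3
  mu <- 0.1
  par <- c(lam + mu, mu / lam, 0.15, 0.1, 0.2, 0.05)
  ll_sse <- sse_loglik(tr, tips, spec, par)
  p <- traitsse:::sse_expand(spec, par)
  mspec <- build_rate_matrix(c("01", "10", "11"), "ARD", root = "uniform")
  mrates <- numeric(mspec$n_free)
  for (i in 1:3) for (j in 1:3) {
    if (mspec$index[i, j] > 0) mrates[mspec$index[i, j]] <- p$Q[i, j]
  }
  ll_mk <- mk_loglik(tr, tips, mspec, mrates)
  expect_equal(ll_sse, oracle_bd_loglik(tr, lam, mu) + ll_mk,
               tolerance = 1e-5)
})

test_that("the likelihood matches an independent fixed-step integrator", {
  tr <- tree2()
  set <- build_model_set("ecotype")
  sp <- set$MuSSE
  tips <- c(A = "01", B = "11")
  par <- c(0.4, 0.55, 0.6, 0.3, 0.2, 0.25, 0.08, 0.05, 0.1, 0.04)
  ll <- sse_loglik(tr, tips, sp, par)
  pars <- traitsse:::sse_expand(sp, par)
  # FitzJohn root in both computations
  ll_oracle <- oracle_sse_loglik(tr, tips, sp, pars, root = "fitzjohn",
                                 h = 1e-5)
  expect_equal(ll, ll_oracle, tolerance = 1e-6)
})

test_that("extinction probabilities vanish when mu = 0 and rho = 1", {
  tr <- tree4()
  spec <- sse_spec("nomu", hidden = 1, tau_map = rep(1L, 3),
                   eps_map = rep(1L, 3),
                   q_map = traitsse:::sse_default_qmap(c("01", "10", "11"), 1),
                   rho = c("01" = 1, "10" = 1, "11" = 1))
  tips <- c(A = "01", B = "11", C = "10", D = "11")
  pars <- list(lambda = rep(0.3, 3), mu = rep(0, 3),
               Q = traitsse:::sse_expand(
                 spec, c(0.3, 1e-9, .1, .1, .1, .1))$Q)
  res <- traitsse:::sse_backbone(tr, tips, spec, pars)
  expect_equal(res$rootE, rep(0, 3), tolerance = 1e-10)
})

test_that("fitting is deterministic under a fixed seed and near-optimal", {
  sc <- sim_scenario("sse", lambda = c(0.2, 0.4, 0.3), mu = rep(0.03, 3),
                     q = sse_scenario_q(0.05, 0)[1:3, 1:3],
                     target_tips = 50, obs_map = c("01", "10", "11"))
  s <- simulate_sse_tree(sc, seed = 19)
  set <- build_model_set("size", rho = c("01" = 1, "10" = 1, "11" = 1))
  f1 <- fit_sse(s$tree, s$tip_states, set$MuSSE, n_starts = 2, seed = 8)
  f2 <- fit_sse(s$tree, s$tip_states, set$MuSSE, n_starts = 2, seed = 8)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)

  # optimum at least as good as the generating parameters
  gen <- c(0.23, 0.43, 0.33,                       # tau = lambda + mu
           0.03 / 0.2, 0.03 / 0.4, 0.03 / 0.3,    # eps
           rep(0.05, 4))
  ll_gen <- sse_loglik(s$tree, s$tip_states, set$MuSSE, gen)
  expect_gte(f1$loglik, ll_gen - 1e-3)
})

test_that("AIC ranking and weights behave like Akaike weights must", {
  one <- rank_models(c(m = 123.4))
  expect_equal(one$weight, 1)
  expect_equal(one$delta_AIC, 0)

  aic <- c(a = 100, b = 102, c = 108)
  r1 <- rank_models(aic)
  r2 <- rank_models(aic + 57.3)
  expect_equal(r1$weight, r2$weight, tolerance = 1e-12)
  expect_equal(sum(r1$weight), 1, tolerance = 1e-10)
  expect_equal(r1$model[1], "a")
  expect_true(all(diff(r1$weight) <= 1e-15))
})

test_that("model-averaged rates are convex combinations", {
  sc <- sim_scenario("sse", lambda = rep(0.3, 3), mu = rep(0.05, 3),
                     q = sse_scenario_q(0.05, 0)[1:3, 1:3],
                     target_tips = 30, obs_map = c("01", "10", "11"))
  s <- simulate_sse_tree(sc, seed = 77)
  set <- build_model_set("size", rho = c("01" = 1, "10" = 1, "11" = 1))
  fits <- list(fit_sse(s$tree, s$tip_states, set$Dull, n_starts = 1, seed = 1),
               fit_sse(s$tree, s$tip_states, set$MuSSE, n_starts = 1, seed = 1))
  recs <- lapply(seq_along(fits), function(i)
    marginal_reconstruction_sse(s$tree, s$tip_states, set[[fits[[i]]$model]],
                                fits[[i]]$par))
  avg <- model_average_rates(fits, recs, min_weight = 0)
  lo <- min(vapply(fits, function(f) min(f$pars$lambda - f$pars$mu),
                   numeric(1)))
  hi <- max(vapply(fits, function(f) max(f$pars$lambda - f$pars$mu),
                   numeric(1)))
  expect_true(all(avg$net_div >= lo - 1e-9 & avg$net_div <= hi + 1e-9))

  # single-model average returns that model's rates
  avg1 <- model_average_rates(fits[1], recs[1], min_weight = 0)
  f <- fits[[1]]
  expect_equal(avg1$net_div,
               as.vector(recs[[1]]$composite %*% (f$pars$lambda - f$pars$mu)),
               tolerance = 1e-10)
  expect_error(model_average_rates(fits, list(NULL, NULL), min_weight = 0.01),
               "missing reconstruction")
})

test_that("marginal SSE reconstruction is normalized and hits limits", {
  tr <- tree4()
  set <- build_model_set("size", rho = c("01" = 1, "10" = 1, "11" = 1))
  sp <- set$MuSSE
  tips <- c(A = "11", B = "11", C = "11", D = "11")
  par <- c(rep(0.3, 3), rep(0.1, 3), rep(1e-8, 4))
  rec <- marginal_reconstruction_sse(tr, tips, sp, par)
  expect_equal(unname(rowSums(rec$composite)), rep(1, 3), tolerance = 1e-8)
  expect_true(all(rec$observed[, "11"] >= 0.99))

  # agreement with the independent-integrator oracle on a 4-tip fixture
  tips2 <- c(A = "01", B = "11", C = "10", D = "11")
  par2 <- c(0.35, 0.5, 0.4, 0.15, 0.1, 0.2, 0.12, 0.08, 0.15, 0.05)
  rec2 <- marginal_reconstruction_sse(tr, tips2, sp, par2)
  pars2 <- traitsse:::sse_expand(sp, par2)
  for (node in 5:7) {
    lls <- vapply(1:3, function(i) {
      mask <- rep(0, 3)
      mask[i] <- 1
      oracle_sse_loglik(tr, tips2, sp, pars2, root = "fitzjohn", h = 1e-4,
                        force_node = node, force_mask = mask)
    }, numeric(1))
    post <- exp(lls - max(lls))
    post <- post / sum(post)
    expect_equal(unname(rec2$composite[node - 4, ]), post, tolerance = 1e-5)
  }
})
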