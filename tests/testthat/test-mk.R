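test_that("rate-matrix factory produces the documented sharing structures", {
  expect_equal(build_rate_matrix(sml_alphabet, "ER")$n_free, 1)
  expect_equal(build_rate_matrix(sml_alphabet, "SYM")$n_free, 3)
  expect_equal(build_rate_matrix(sml_alphabet, "ARD")$n_free, 6)

  con <- build_rate_matrix(sml_alphabet, "ARD", constrained = TRUE)
  expect_equal(con$n_free, 4)
  expect_equal(con$index["S", "L"], 0L)
  expect_equal(con$index["L", "S"], 0L)
  Q <- traitsse:::mk_Q(con, c(.1, .2, .3, .4))
  expect_equal(Q["S", "L"], 0)
  expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)

  expect_error(build_rate_matrix(c("A", "B", "C"), "ARD", constrained = TRUE),
               "intermediate")
})

test_that("zero rates reduce the likelihood to the root prior", {
  spec <- build_rate_matrix(sml_alphabet, "ER", root = "uniform")
  tips <- c(A = "S", B = "S", C = "S", D = "S")
  expect_equal(mk_loglik(tree4(), tips, spec, 1e-15), log(1 / 3),
               tolerance = 1e-9)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(2)
  for (tr in list(tree3(), tree4())) {
    for (model in c("ER", "SYM", "ARD")) {
      for (constrained in c(FALSE, TRUE)) {
        spec <- build_rate_matrix(sml_alphabet, model,
                                  constrained = constrained,
                                  root = "uniform")
        rates <- stats::runif(spec$n_free, 0.05, 0.6)
        tips <- stats::setNames(sample(sml_alphabet, length(tr$tip.label),
                                       replace = TRUE), tr$tip.label)
        Q <- traitsse:::mk_Q(spec, rates)
        expect_equal(mk_loglik(tr, tips, spec, rates),
                     oracle_mk_loglik(tr, tips, sml_alphabet, Q,
                                      rep(1 / 3, 3)),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("infinitely long branches decouple tips (stationary limit)", {
  spec <- build_rate_matrix(sml_alphabet, "ER", root = "stationary")
  r <- 0.5
  tr <- read_tree(sprintf("((A:%g,B:%g):%g,C:%g);",
                          1e4 / r, 1e4 / r, 1e4 / r, 2e4 / r))
  tips <- c(A = "S", B = "M", C = "L")
  expect_equal(mk_loglik(tr, tips, spec, r), 3 * log(1 / 3),
               tolerance = 1e-6)
})

test_that("ML fits respect model nesting", {
  tr <- yule_tree(60, seed = 12)
  er <- build_rate_matrix(sml_alphabet, "ER")
  sim <- simulate_mk_traits(tr, er, 0.4, seed = 3)
  fits <- lapply(c("ER", "SYM", "ARD"), function(mod)
    fit_mk(tr, sim$tip_states, build_rate_matrix(sml_alphabet, mod),
           n_starts = 4, seed = 5))
  expect_gte(fits[[3]]$loglik, fits[[2]]$loglik - 1e-6)
  expect_gte(fits[[2]]$loglik, fits[[1]]$loglik - 1e-6)

  con <- fit_mk(tr, sim$tip_states,
                build_rate_matrix(sml_alphabet, "ARD", constrained = TRUE),
                n_starts = 4, seed = 5)
  expect_lte(con$loglik, fits[[3]]$loglik + 1e-6)
})

test_that("the ER rate is recovered from simulated data", {
  errs <- vapply(1:10, function(i) {
    tr <- yule_tree(200, seed = 100 + i)
    tr$edge.length <- tr$edge.length / max(node_depths(tr)[1:200]) * 5
    spec <- build_rate_matrix(sml_alphabet, "ER")
    sim <- simulate_mk_traits(tr, spec, 0.3, seed = 200 + i)
    fit <- fit_mk(tr, sim$tip_states, spec, n_starts = 3, seed = 1)
    abs(fit$rates[1] - 0.3) / 0.3
  }, numeric(1))
  expect_lt(stats::median(errs), 0.3)
})

test_that("single observed state warns and fits at the boundary", {
  spec <- build_rate_matrix(sml_alphabet, "ER")
  expect_warning(
    fit <- fit_mk(tree4(), c(A = "S", B = "S", C = "S", D = "S"), spec,
                  n_starts = 2, seed = 1),
    "one observed state")
  expect_lt(fit$rates[1], 1e-6)
})
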