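test_that("pure-birth simulation matches the exponential-growth expectation", {
  sc <- sim_scenario("yule", lambda = 0.3, stop_time = 3)
  set.seed(123)
  tips <- vapply(1:300, function(i) {
    s <- tryCatch(simulate_sse_tree(sc), error = function(e) NULL)
    if (is.null(s)) NA_real_ else length(s$tree$tip.label)
  }, numeric(1))
  # E[tips | survival to t] is close to 2 exp(lambda t) for pure birth
  # (no extinction, so no conditioning bias)
  expected <- 2 * exp(0.3 * 3)
  se <- stats::sd(tips, na.rm = TRUE) / sqrt(sum(!is.na(tips)))
  expect_lt(abs(mean(tips, na.rm = TRUE) - expected), 4 * se + 0.2)
})

test_that("a zero-speciation scenario cannot reach a tip target", {
  sc <- sim_scenario("yule", lambda = 0, target_tips = 10, max_attempts = 5)
  expect_error(simulate_sse_tree(sc, seed = 1), "attempts")
})

test_that("symmetric transition rates give near-uniform tip states", {
  q <- matrix(0.08, 3, 3)
  diag(q) <- 0
  sc <- sim_scenario("sse", lambda = rep(0.3, 3), mu = rep(0, 3), q = q,
                     target_tips = 40, obs_map = c("01", "10", "11"))
  set.seed(9)
  freq <- rowMeans(vapply(1:120, function(i) {
    s <- simulate_sse_tree(sc)
    tabulate(s$tip_state_idx, 3) / length(s$tip_state_idx)
  }, numeric(3)))
  expect_true(all(abs(freq - 1 / 3) < 0.06))
})

test_that("simulated trees are ultrametric with exact branch histories", {
  sc <- sim_scenario("sse", lambda = c(0.25, 0.35, 0.3), mu = rep(0.05, 3),
                     q = sse_scenario_q(0.06, 0)[1:3, 1:3],
                     target_tips = 70, obs_map = c("01", "10", "11"))
  s <- simulate_sse_tree(sc, seed = 15)
  expect_true(check_ultrametric(s$tree)$ultrametric)
  lens <- vapply(s$histories, function(h) sum(h$duration), numeric(1))
  expect_equal(lens, s$tree$edge.length, tolerance = 1e-9)
  # structurally masked direct extreme moves never occur in true histories
  expect_equal(s$true_counts[1, 2], 0L)
  expect_equal(s$true_counts[2, 1], 0L)
  expect_true(all(diag(s$true_counts) == 0))
  # tip states concur with the last segment of each terminal history
  n_tip <- length(s$tree$tip.label)
  for (k in seq_len(nrow(s$tree$edge))) {
    ch <- s$tree$edge[k, 2]
    if (ch <= n_tip) {
      h <- s$histories[[k]]
      expect_equal(unname(s$tip_state_idx[ch]), h$state[nrow(h)])
    }
  }
})

test_that("Mk trait simulation honours rates, masks and closed forms", {
  spec <- build_rate_matrix(sml_alphabet, "ER")
  tr <- yule_tree(20, seed = 70)
  sim0 <- simulate_mk_traits(tr, spec, 1e-12, seed = 71)
  expect_length(unique(sim0$tip_states), 1)
  expect_true(all(sim0$true_counts == 0))

  # 2-state disagreement probability across one branch of length t:
  # (1 - exp(-2 r t)) / 2
  spec2 <- build_rate_matrix(c("A", "B"), "ER")
  tb <- read_tree("(X:1.3,Y:0.0001);")
  r <- 0.4
  set.seed(72)
  dis <- vapply(1:4000, function(i) {
    s <- simulate_mk_traits(tb, spec2, r)
    s$tip_states[["X"]] != s$tip_states[["Y"]]
  }, logical(1))
  p_expected <- (1 - exp(-2 * r * 1.3)) / 2
  se <- sqrt(p_expected * (1 - p_expected) / 4000)
  expect_lt(abs(mean(dis) - p_expected), 4 * se)

  # masked transitions never appear in true histories
  con <- build_rate_matrix(sml_alphabet, "ARD", constrained = TRUE)
  sim2 <- simulate_mk_traits(yule_tree(60, seed = 73), con,
                             c(.3, .3, .3, .3), seed = 74)
  expect_equal(sim2$true_counts["S", "L"], 0L)
  expect_equal(sim2$true_counts["L", "S"], 0L)
})

test_that("continuous simulation reproduces the target covariance", {
  tr <- yule_tree(8, seed = 80)
  C <- ape::vcv.phylo(tr)
  set.seed(81)
  X <- vapply(1:2000, function(i)
    simulate_continuous_traits(tr, sig2 = 1.5, lambda = 1)[rownames(C)],
    numeric(8))
  S <- stats::cov(t(X))
  expect_lt(norm(S - 1.5 * C, "F") / norm(1.5 * C, "F"), 0.10)

  # lambda = 0: tips uncorrelated
  set.seed(82)
  X0 <- vapply(1:2000, function(i)
    simulate_continuous_traits(tr, sig2 = 1, lambda = 0)[rownames(C)],
    numeric(8))
  R <- stats::cor(t(X0))
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)

  expect_identical(simulate_continuous_traits(tr, seed = 5),
                   simulate_continuous_traits(tr, seed = 5))
})

test_that("the fixture suite regenerates byte-identically with a manifest", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  m1 <- make_fixture_suite(d1, seed = 11)
  m2 <- make_fixture_suite(d2, seed = 11)
  files <- names(m1$files)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  expect_identical(readLines(file.path(d1, "manifest.json"), warn = FALSE),
                   readLines(file.path(d2, "manifest.json"), warn = FALSE))
  # the recorded tip-state counts match the shipped state table
  states <- utils::read.csv(file.path(d1, "sse300_states.csv"),
                            colClasses = "character")
  rec <- m1$files[["sse300.nwk"]]$tip_state_counts
  expect_equal(as.list(table(states$code))[names(rec)],
               lapply(rec, as.integer))
  unlink(c(d1, d2), recursive = TRUE)
})
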