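test_that("zero rates give transition-free maps; seeds give identical maps", {
  spec <- build_rate_matrix(sml_alphabet, "ER", root = "uniform")
  tips <- c(A = "M", B = "M", C = "M", D = "M")
  maps <- sample_stochastic_maps(tree4(), tips, spec, 1e-10, M = 20, seed = 3)
  expect_true(all(maps$counts == 0))

  spec2 <- build_rate_matrix(sml_alphabet, "ARD")
  tr <- yule_tree(30, seed = 14)
  sim <- simulate_mk_traits(tr, spec2, rep(0.25, 6), seed = 8)
  a <- sample_stochastic_maps(tr, sim$tip_states, spec2, rep(0.25, 6),
                              M = 10, seed = 42)
  b <- sample_stochastic_maps(tr, sim$tip_states, spec2, rep(0.25, 6),
                              M = 10, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$node_states, b$node_states)
})

test_that("segment durations conserve branch lengths exactly", {
  spec <- build_rate_matrix(sml_alphabet, "ARD")
  tr <- yule_tree(25, seed = 4)
  sim <- simulate_mk_traits(tr, spec, rep(0.3, 6), seed = 5)
  maps <- sample_stochastic_maps(tr, sim$tip_states, spec, rep(0.3, 6),
                                 M = 5, seed = 6)
  for (r in 1:5) {
    lens <- vapply(maps$maps[[r]], function(h) sum(h$duration), numeric(1))
    expect_equal(lens, tr$edge.length, tolerance = 1e-12)
    # consecutive segments always differ in state
    for (h in maps$maps[[r]]) {
      if (nrow(h) > 1) expect_true(all(diff(h$state) != 0))
    }
  }
  # tip-end state equals the observed state
  for (r in 1:5) {
    for (k in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[k, 2]
      if (ch <= 25) {
        h <- maps$maps[[r]][[k]]
        expect_equal(maps$states[h$state[nrow(h)]],
                     unname(sim$tip_states[tr$tip.label[ch]]))
      }
    }
  }
})

test_that("masked transitions never occur in sampled histories", {
  spec <- build_rate_matrix(sml_alphabet, "ARD", constrained = TRUE)
  tr <- yule_tree(40, seed = 9)
  sim <- simulate_mk_traits(tr, spec, c(.3, .35, .3, .2), seed = 10)
  maps <- sample_stochastic_maps(tr, sim$tip_states, spec,
                                 c(.3, .35, .3, .2), M = 40, seed = 11)
  ct <- count_transitions(maps)
  expect_true(all(ct$per_map["S", "L", ] == 0))
  expect_true(all(ct$per_map["L", "S", ] == 0))
  expect_equal(ct$mean["S", "L"], 0)
  expect_equal(ct$modal["L", "S"], 0L)
})

test_that("conditional branch histories match the uniformization moments", {
  rate <- 0.35
  t <- 1.6
  Q <- matrix(c(-rate, rate, rate, -rate), 2, 2)
  P <- traitsse:::mat_exp(Q * t)
  omega <- rate
  Rm <- diag(2) + Q / omega
  rpow_env <- new.env()
  assign("p", list(diag(2)), envir = rpow_env)
  Rpower <- function(n) {
    p <- get("p", envir = rpow_env)
    while (length(p) < n + 1) p[[length(p) + 1]] <- p[[length(p)]] %*% Rm
    assign("p", p, envir = rpow_env)
    p[[n + 1]]
  }
  set.seed(77)
  changes <- vapply(1:5000, function(i) {
    h <- traitsse:::sample_branch_history(1, 1, t, Q, P, omega, Rm, Rpower)
    nrow(h) - 1
  }, numeric(1))
  exp_changes <- oracle_conditional_changes_2state(1, 1, t, rate)
  se <- stats::sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes) - exp_changes), 4 * se + 1e-3)

  # endpoints differing: at least one change in every history
  set.seed(78)
  h2 <- traitsse:::sample_branch_history(1, 2, t, Q, P, omega, Rm, Rpower)
  expect_gte(nrow(h2), 2)
  expect_equal(h2$state[1], 1)
  expect_equal(h2$state[nrow(h2)], 2)
})

test_that("SIMMAP export annotates every branch", {
  spec <- build_rate_matrix(sml_alphabet, "ER")
  tips <- c(A = "S", B = "M", C = "L", D = "M")
  maps <- sample_stochastic_maps(tree4(), tips, spec, 0.4, M = 2, seed = 1)
  s <- write_simmap(maps)
  expect_length(s, 2)
  expect_true(all(grepl("^\\(.*\\{.*\\}.*;$", s)))
})
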