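# Independent oracles: brute-force / closed-form / high-resolution
# reference computations the implementation is checked against. These share
# no code with the package internals (matrix exponentials by
# eigendecomposition, fixed-step RK4 for the SSE system, exhaustive state
# enumeration).

# matrix exponential by eigendecomposition (independent of the package
# scaling-and-squaring routine); generic rate matrices are diagonalizable
oracle_expm <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values), nrow(A)) %*% solve(e$vectors))
}

# --- gap coding: enumerate all (k-1)-breakpoint placements, maximize the
# summed widths of the chosen gaps; ties broken toward smaller values
oracle_gap_breaks <- function(values, k) {
  v <- sort(unique(values[!is.na(values)]))
  if (k == 1) return(numeric(0))
  gaps <- diff(v)
  combs <- utils::combn(seq_along(gaps), k - 1)
  widths <- apply(combs, 2, function(ix) sum(gaps[ix]))
  best <- max(widths)
  # among maximal placements pick the lexicographically smallest index set
  cand <- which(abs(widths - best) < 1e-12)
  ordc <- do.call(order, as.data.frame(t(combs[, cand, drop = FALSE])))
  pick <- cand[ordc[1]]
  ix <- sort(combs[, pick])
  (v[ix] + v[ix + 1]) / 2
}

# --- Mk likelihood by exhaustive enumeration over internal-node states
# (root prior explicit)
oracle_mk_loglik <- function(tree, tip_states, states, Q, root_prior) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  m <- length(states)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    oracle_expm(Q * tree$edge.length[k]))
  tip_idx <- match(tip_states[tree$tip.label], states)
  assigns <- as.matrix(expand.grid(rep(list(seq_len(m)), n_int)))
  total <- 0
  for (r in seq_len(nrow(assigns))) {
    st <- c(tip_idx, assigns[r, ])
    lik <- root_prior[st[n_tip + 1]]
    for (k in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[k]][st[tree$edge[k, 1]], st[tree$edge[k, 2]]]
    }
    total <- total + lik
  }
  log(total)
}

# posterior of each state at one internal node, by the same enumeration
oracle_mk_marginal <- function(tree, tip_states, states, Q, root_prior,
                               node) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  m <- length(states)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    oracle_expm(Q * tree$edge.length[k]))
  tip_idx <- match(tip_states[tree$tip.label], states)
  assigns <- as.matrix(expand.grid(rep(list(seq_len(m)), n_int)))
  post <- numeric(m)
  for (r in seq_len(nrow(assigns))) {
    st <- c(tip_idx, assigns[r, ])
    lik <- root_prior[st[n_tip + 1]]
    for (k in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[k]][st[tree$edge[k, 1]], st[tree$edge[k, 2]]]
    }
    post[st[node]] <- post[st[node]] + lik
  }
  post / sum(post)
}

# --- constant-rate birth-death log-likelihood (rho = 1, crown start,
# conditioned on survival of both root lineages), closed form
oracle_bd_loglik <- function(tree, lambda, mu) {
  nh <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  depth <- max(nh[seq_len(n_tip)])
  age <- depth - nh
  r <- lambda - mu
  Efun <- function(t) {
    if (mu == 0) return(rep(0, length(t)))
    mu * (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
  }
  acc <- 0
  for (k in seq_len(nrow(tree$edge))) {
    t1 <- age[tree$edge[k, 2]]
    t2 <- age[tree$edge[k, 1]]
    acc <- acc + (-r * (t2 - t1)) +
      2 * (log(1 - Efun(t2)) - log(1 - Efun(t1)))
  }
  acc + (n_tip - 1) * log(lambda) - log(lambda) -
    2 * log(1 - Efun(depth))
}

# --- SSE likelihood by classic fixed-step 4th-order Runge-Kutta, written
# independently of the package integrator
oracle_sse_deriv <- function(y, lambda, mu, Q) {
  ns <- length(lambda)
  E <- y[seq_len(ns)]
  D <- y[ns + seq_len(ns)]
  qout <- rowSums(Q)
  tot <- lambda + mu + qout
  dE <- mu - tot * E + lambda * E^2 + as.vector(Q %*% E)
  dD <- -tot * D + 2 * lambda * E * D + as.vector(Q %*% D)
  c(dE, dD)
}

oracle_rk4 <- function(y, tlen, lambda, mu, Q, h = 1e-4) {
  nstep <- max(1L, ceiling(tlen / h))
  h <- tlen / nstep
  for (i in seq_len(nstep)) {
    k1 <- oracle_sse_deriv(y, lambda, mu, Q)
    k2 <- oracle_sse_deriv(y + h / 2 * k1, lambda, mu, Q)
    k3 <- oracle_sse_deriv(y + h / 2 * k2, lambda, mu, Q)
    k4 <- oracle_sse_deriv(y + h * k3, lambda, mu, Q)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# full-tree SSE log-likelihood with the RK4 oracle (FitzJohn or uniform
# root, survival conditioning), optionally restricting one node's state set
oracle_sse_loglik <- function(tree, tip_codes, spec, pars,
                              root = "uniform", h = 1e-4,
                              force_node = 0, force_mask = NULL) {
  ns <- spec$ns
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  rho_comp <- spec$rho[spec$comp_obs]
  E <- matrix(NA_real_, n_node, ns)
  D <- matrix(NA_real_, n_node, ns)
  codes <- tip_codes[tree$tip.label]
  for (i in seq_len(n_tip)) {
    E[i, ] <- 1 - rho_comp
    D[i, ] <- ifelse(spec$comp_obs == codes[i], rho_comp, 0)
    if (force_node == i) D[i, ] <- D[i, ] * force_mask
  }
  Qod <- pars$Q
  diag(Qod) <- 0
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  nseen <- integer(n_node)
  nchild <- tabulate(tree$edge[, 1], nbins = n_node)
  for (k in po) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    y <- oracle_rk4(c(E[ch, ], D[ch, ]), tree$edge.length[k],
                    pars$lambda, pars$mu, Qod, h = h)
    if (nseen[p] == 0) {
      E[p, ] <- y[seq_len(ns)]
      D[p, ] <- y[ns + seq_len(ns)]
    } else {
      D[p, ] <- D[p, ] * pars$lambda * y[ns + seq_len(ns)]
    }
    nseen[p] <- nseen[p] + 1
    if (nseen[p] == nchild[p] && force_node == p) {
      D[p, ] <- D[p, ] * force_mask
    }
  }
  rt <- n_tip + 1
  w <- if (root == "uniform") rep(1 / ns, ns) else D[rt, ] / sum(D[rt, ])
  log(sum(w * D[rt, ] / (pars$lambda * (1 - E[rt, ])^2)))
}

# --- classical one-way ANOVA F by direct two-pass computation
oracle_anova_F <- function(groups, y) {
  groups <- factor(groups)
  grand <- mean(y)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    yg <- y[groups == g]
    ssb <- ssb + length(yg) * (mean(yg) - grand)^2
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  (ssb / (nlevels(groups) - 1)) / (ssw / (length(y) - nlevels(groups)))
}

# --- expected number of (real) state changes on one branch conditional on
# endpoints, 2-state equal-rates model, by the uniformization series
oracle_conditional_changes_2state <- function(a, b, t, rate, nmax = 400) {
  Q <- matrix(c(-rate, rate, rate, -rate), 2, 2)
  P <- oracle_expm(Q * t)
  omega <- rate
  R <- diag(2) + Q / omega
  # E[real changes] = sum_n p(n|a,b) * E[real | n jumps, bridge a->b]
  Rpow <- list(diag(2))
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  total <- 0
  for (n in 0:nmax) {
    if (Rpow[[n + 1]][a, b] == 0) next
    pn <- stats::dpois(n, omega * t) * Rpow[[n + 1]][a, b] / P[a, b]
    if (pn < 1e-14 && n > 10) break
    if (n == 0) next
    # expected real jumps among the n: sum over positions of
    # P(jump z is real | bridge)
    ereal <- 0
    for (z in seq_len(n)) {
      # state before jump z distributed via R^(z-1), after via R^(n-z)
      pz <- 0
      for (s1 in 1:2) for (s2 in 1:2) {
        if (s1 == s2) next
        pz <- pz + Rpow[[z]][a, s1] * R[s1, s2] * Rpow[[n - z + 1]][s2, b] /
          Rpow[[n + 1]][a, b]
      }
      ereal <- ereal + pz
    }
    total <- total + pn * ereal
  }
  total
}
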