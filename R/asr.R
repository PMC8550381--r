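#' Marginal ancestral state reconstruction under an Mk model
#'
#' Computes, for every node, the marginal posterior probability of each state
#' given the tip data and fitted rates, by combining the downward (pruning)
#' partial likelihoods with upward partials obtained by re-rooting passes.
#'
#' @inheritParams mk_loglik
#' @return A matrix (nodes x states) of class `"ancestral_marginals"`; rows
#'   `1..n` are tips (delta distributions for observed tips), the remaining
#'   rows internal nodes in `ape` numbering. Rows sum to 1.
#' @export
marginal_asr <- function(tree, tip_states, spec, rates, root = spec$root) {
  Q <- mk_Q(spec, rates)
  tipL <- mk_tip_partials(tree, tip_states, spec$states)
  pr <- mk_pruning(tree, tipL, Q, root = root)
  n_tip <- nrow(tipL)
  m <- ncol(Q)
  n_node <- n_tip + tree$Nnode
  root_node <- n_tip + 1L
  up <- matrix(0, n_node, m)
  up[root_node, ] <- pr$root_prior
  pre <- reorder_edges_preorder(tree)
  # per-parent list of child edges for sibling products
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  # child-edge messages: M_k[i] = sum_j P_k[i,j] down[child_k, j]
  msg <- t(vapply(seq_len(nrow(tree$edge)), function(k) {
    as.vector(pr$P[[k]] %*% pr$down[tree$edge[k, 2L], ])
  }, numeric(m)))
  for (k in pre) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    sib <- setdiff(kids[[as.character(p)]], k)
    w <- up[p, ]
    for (s in sib) w <- w * msg[s, ]
    u <- as.vector(w %*% pr$P[[k]])  # sum_i w_i P[i, j]
    su <- sum(u)
    up[ch, ] <- if (su > 0) u / su else u
  }
  marg <- up * pr$down
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(c(tree$tip.label, paste0("node", root_node:n_node)),
                         spec$states)
  structure(marg, class = c("ancestral_marginals", "matrix"))
}
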