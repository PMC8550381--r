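#' Sample stochastic character maps
#'
#' Draws full character histories conditional on the tip data and a fitted
#' Mk model: node states are sampled from their joint conditional
#' distribution (backward pruning, forward sampling) and within-branch
#' histories conditional on the branch endpoints by uniformization, which
#' remains exact when endpoint states differ and rates are small. Structural
#' zeros of the model can never be crossed.
#'
#' @inheritParams mk_loglik
#' @param M Number of maps to sample.
#' @param seed Integer seed; fixed seed gives identical maps.
#' @param max_retries Retries when an endpoint pair has (numerically) zero
#'   path probability before erroring.
#' @return Object of class `"simmap_set"`: `maps` (list of `M` histories;
#'   each a list per edge of a data.frame with `state` and `duration`,
#'   ordered rootward to tipward), `node_states` (`M x nodes` matrix),
#'   `states`, `tree`, and the per-map transition `counts` array
#'   (`m x m x M`).
#' @export
sample_stochastic_maps <- function(tree, tip_states, spec, rates, M = 100,
                                   seed = NULL, root = spec$root,
                                   max_retries = 100) {
  stopifnot(M >= 1)
  if (!is.null(seed)) set.seed(seed)
  Q <- mk_Q(spec, rates)
  m <- spec$m
  tipL <- mk_tip_partials(tree, tip_states, spec$states)
  pr <- mk_pruning(tree, tipL, Q, root = root)
  n_tip <- nrow(tipL)
  n_node <- n_tip + tree$Nnode
  root_node <- n_tip + 1L
  pre <- reorder_edges_preorder(tree)
  root_post <- pr$root_prior * pr$down[root_node, ]
  root_post <- root_post / sum(root_post)
  omega <- max(-diag(Q))
  Rm <- if (omega > 0) diag(m) + Q / omega else diag(m)
  rpow <- new.env(parent = emptyenv())
  assign("p", list(diag(m)), envir = rpow)  # p[[n+1]] = R^n
  Rpower <- function(n) {
    p <- get("p", envir = rpow)
    while (length(p) < n + 1) p[[length(p) + 1]] <- p[[length(p)]] %*% Rm
    assign("p", p, envir = rpow)
    p[[n + 1]]
  }
  maps <- vector("list", M)
  node_states <- matrix(NA_integer_, M, n_node)
  counts <- array(0L, dim = c(m, m, M),
                  dimnames = list(spec$states, spec$states, NULL))
  for (r in seq_len(M)) {
    st <- integer(n_node)
    st[root_node] <- sample.int(m, 1, prob = root_post)
    hist_edges <- vector("list", nrow(tree$edge))
    for (k in pre) {
      p_nd <- tree$edge[k, 1L]
      ch <- tree$edge[k, 2L]
      a <- st[p_nd]
      w <- pr$P[[k]][a, ] * pr$down[ch, ]
      if (sum(w) <= 0) {
        stop("zero-probability endpoint combination on edge ", k, call. = FALSE)
      }
      b <- sample.int(m, 1, prob = w)
      st[ch] <- b
      hist_edges[[k]] <- sample_branch_history(
        a, b, tree$edge.length[k], Q, pr$P[[k]], omega, Rm, Rpower,
        max_retries)
      tr <- hist_edges[[k]]$state
      if (length(tr) > 1) {
        for (z in seq_len(length(tr) - 1)) {
          counts[tr[z], tr[z + 1], r] <- counts[tr[z], tr[z + 1], r] + 1L
        }
      }
    }
    maps[[r]] <- hist_edges
    node_states[r, ] <- st
  }
  structure(list(maps = maps, node_states = node_states,
                 states = spec$states, tree = tree, counts = counts,
                 spec = spec, rates = rates),
            class = "simmap_set")
}

# conditional path on one branch by uniformization: draw the number of
# (possibly virtual) jumps from its exact conditional distribution, place
# jump times uniformly, sample the embedded chain bridge, drop virtual jumps
sample_branch_history <- function(a, b, t, Q, P, omega, Rm, Rpower,
                                  max_retries = 100) {
  m <- nrow(Q)
  if (t <= 0 || omega == 0) {
    if (a != b) stop("state change required on a zero-length branch",
                     call. = FALSE)
    return(data.frame(state = a, duration = t))
  }
  pab <- P[a, b]
  if (pab <= 0) stop("endpoint pair has zero path probability", call. = FALSE)
  ot <- omega * t
  # N | a,b,t : p(n) = dpois(n, ot) * (R^n)[a,b] / pab
  u <- stats::runif(1)
  n <- -1L
  cum <- 0
  repeat {
    n <- n + 1L
    cum <- cum + stats::dpois(n, ot) * Rpower(n)[a, b] / pab
    if (cum >= u || n > 10000L) break
  }
  if (n > 10000L) stop("uniformization failed to converge (rate too high?)",
                       call. = FALSE)
  path <- a
  if (n > 0) {
    for (z in seq_len(n)) {
      if (z == n) {
        path <- c(path, b)
      } else {
        w <- Rm[path[z], ] * Rpower(n - z)[, b]
        path <- c(path, sample.int(m, 1, prob = w))
      }
    }
  }
  times <- c(0, sort(stats::runif(n)) * t, t)
  # merge virtual (self) jumps into segments
  state <- path[1]
  dur <- numeric(0)
  seg_start <- 0
  for (z in seq_len(n)) {
    if (path[z + 1] != path[z]) {
      dur <- c(dur, times[z + 1] - seg_start)
      state <- c(state, path[z + 1])
      seg_start <- times[z + 1]
    }
  }
  dur <- c(dur, t - seg_start)
  data.frame(state = state, duration = dur)
}

#' Transition counts from stochastic maps
#'
#' Summarizes the sampled histories of a [sample_stochastic_maps()] set as
#' per-map integer transition-count matrices plus their mean and modal
#' counts across maps. Structurally masked transitions are always 0.
#'
#' @param maps A `"simmap_set"`.
#' @return A list with `per_map` (`m x m x M` integer array), `mean`, and
#'   `modal` (per-cell most frequent count) matrices, labelled by state.
#' @export
count_transitions <- function(maps) {
  stopifnot(inherits(maps, "simmap_set"))
  cm <- maps$counts
  mean_m <- apply(cm, c(1, 2), mean)
  modal_m <- apply(cm, c(1, 2), function(v) {
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  })
  list(per_map = cm, mean = mean_m, modal = modal_m)
}

#' @export
print.simmap_set <- function(x, ...) {
  cat(dim(x$counts)[3], "stochastic maps on", length(x$tree$tip.label),
      "tips;", length(x$states), "states\n")
  cat("mean transition counts:\n")
  print(round(apply(x$counts, c(1, 2), mean), 2))
  invisible(x)
}

#' Export stochastic maps as SIMMAP-annotated Newick strings
#'
#' @param maps A `"simmap_set"`.
#' @param which Indices of maps to export.
#' @return Character vector of SIMMAP-style Newick strings, one per map,
#'   with branch annotations `{state,duration:state,duration...}` ordered
#'   rootward to tipward.
#' @export
write_simmap <- function(maps, which = seq_along(maps$maps)) {
  tree <- maps$tree
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  vapply(which, function(r) {
    h <- maps$maps[[r]]
    lab_edge <- function(k) {
      seg <- h[[k]]
      paste0("{", paste(sprintf("%s,%.8g", maps$states[seg$state],
                                seg$duration), collapse = ":"), "}")
    }
    build <- function(nd) {
      if (nd <= n_tip) return(tree$tip.label[nd])
      ke <- kids[[as.character(nd)]]
      parts <- vapply(ke, function(k) {
        paste0(build(tree$edge[k, 2L]), ":", lab_edge(k))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    paste0(build(n_tip + 1L), ";")
  }, character(1))
}
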