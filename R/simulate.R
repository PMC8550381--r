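#' Describe a simulation scenario
#'
#' Bundles the generator choice and all parameters of a synthetic dataset so
#' a scenario plus a seed reproduces identical output. For the `"sse"`
#' generator, states evolve anagenetically with rates `q` while lineages
#' speciate/go extinct at state-dependent rates; `"yule"` and `"bd"` are the
#' single-state special cases.
#'
#' @param generator One of `"yule"`, `"bd"`, `"sse"`.
#' @param lambda Per-state speciation rates (events/my).
#' @param mu Per-state extinction rates.
#' @param q Transition-rate matrix among states (ignored for 1 state).
#' @param target_tips Extant tip count at which the simulation stops
#'   (mutually exclusive with `stop_time`).
#' @param stop_time Fixed simulation duration (my).
#' @param rho Per-state sampling fractions applied to extant tips.
#' @param obs_map Optional character vector mapping simulation states to
#'   observed labels (e.g. composite -> binary-pair codes); defaults to
#'   `"s1".."sk"`.
#' @param tip_window Relative acceptance window around the expected sampled
#'   tip count (default +/- 20%).
#' @param max_attempts Retry budget for whole-clade extinction/window
#'   rejections.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(generator = c("sse", "yule", "bd"),
                         lambda = 0.2, mu = 0, q = NULL,
                         target_tips = NULL, stop_time = NULL,
                         rho = 1, obs_map = NULL,
                         tip_window = 0.2, max_attempts = 1000) {
  generator <- match.arg(generator)
  k <- length(lambda)
  if (length(mu) == 1) mu <- rep(mu, k)
  stopifnot(length(mu) == k, all(lambda >= 0), all(mu >= 0))
  if (is.null(q)) q <- matrix(0, k, k)
  stopifnot(all(dim(q) == k), all(q[!diag(k)] >= 0))
  if (length(rho) == 1) rho <- rep(rho, k)
  stopifnot(length(rho) == k, all(rho > 0), all(rho <= 1))
  if (is.null(obs_map)) obs_map <- paste0("s", seq_len(k))
  if (is.null(target_tips) == is.null(stop_time)) {
    stop("give exactly one of target_tips or stop_time", call. = FALSE)
  }
  structure(list(generator = generator, lambda = lambda, mu = mu, q = q,
                 k = k, target_tips = target_tips, stop_time = stop_time,
                 rho = rho, obs_map = obs_map, tip_window = tip_window,
                 max_attempts = max_attempts),
            class = "sim_scenario")
}

#' Simulate a tree under a (state-dependent) birth-death process
#'
#' Forward event-driven simulation from a crown root of two lineages:
#' lineages speciate, go extinct and change state anagenetically at the
#' scenario's rates. Extinct lineages are pruned, extant tips are subsampled
#' by their state's sampling fraction, and the reconstructed ultrametric
#' tree is returned together with the observed tip states and the true
#' per-branch state histories (so transition counting can be validated
#' without inference). Whole-clade extinctions and trees outside the
#' tip-count window are rejected and retried within the attempt budget.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed.
#' @param root_state Starting state index (default sampled uniformly).
#' @return A list of class `"sim_tree"`: `tree` (`phylo`), `tip_states`
#'   (named observed labels), `tip_state_idx`, `histories` (per-edge
#'   data.frames of `state`, `duration`, root-to-tip order), `node_states`
#'   (true state index at each node), `true_counts` (k x k transition counts
#'   along retained branches), `attempts`.
#' @export
simulate_sse_tree <- function(scenario, seed = NULL, root_state = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  for (att in seq_len(scenario$max_attempts)) {
    sim <- sim_forward_once(scenario, root_state)
    if (is.null(sim)) next
    out <- sim_reconstruct(sim, scenario)
    if (is.null(out)) next
    out$attempts <- att
    return(out)
  }
  stop("no acceptable tree in ", scenario$max_attempts,
       " attempts; the scenario may be too extinction-prone or the tip ",
       "window too narrow", call. = FALSE)
}

# one forward pass; returns NULL on whole-clade extinction (or no
# speciation possible for a tip target)
sim_forward_once <- function(sc, root_state) {
  k <- sc$k
  qout <- rowSums(sc$q) - diag(sc$q)
  tot <- sc$lambda + sc$mu + qout
  if (!is.null(sc$target_tips) && all(sc$lambda == 0) && sc$target_tips >= 2) {
    return(NULL)
  }
  rs <- if (is.null(root_state)) sample.int(k, 1) else root_state
  # lineage registry
  cap <- 64L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  state <- integer(cap); status <- character(cap)
  hist <- vector("list", cap)
  n_lin <- 2L
  parent[1:2] <- 0L; t0[1:2] <- 0; state[1:2] <- rs
  status[1:2] <- "active"
  hist[[1]] <- data.frame(state = rs, tstart = 0)
  hist[[2]] <- data.frame(state = rs, tstart = 0)
  active <- c(1L, 2L)
  t <- 0
  grow <- function() {
    cap2 <- cap * 2L
    parent <<- c(parent, integer(cap)); t0 <<- c(t0, numeric(cap))
    t1 <<- c(t1, numeric(cap)); state <<- c(state, integer(cap))
    status <<- c(status, character(cap))
    length(hist) <<- cap2
    cap <<- cap2
  }
  end_at <- function(tend) {
    for (id in active) {
      t1[id] <<- tend
      status[id] <<- "extant"
    }
  }
  repeat {
    rates <- tot[state[active]]
    R <- sum(rates)
    if (R <= 0) {
      if (!is.null(sc$stop_time)) {
        end_at(sc$stop_time)
        break
      }
      return(NULL)
    }
    dt <- stats::rexp(1, R)
    if (!is.null(sc$stop_time) && t + dt > sc$stop_time) {
      end_at(sc$stop_time)
      break
    }
    t <- t + dt
    id <- active[sample.int(length(active), 1, prob = rates)]
    s <- state[id]
    ev <- sample.int(3, 1, prob = c(sc$lambda[s], sc$mu[s], qout[s]))
    if (ev == 1) {
      # speciation: id ends, two children begin
      t1[id] <- t; status[id] <- "split"
      while (n_lin + 2L > cap) grow()
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      parent[c(c1, c2)] <- id; t0[c(c1, c2)] <- t; state[c(c1, c2)] <- s
      status[c(c1, c2)] <- "active"
      hist[[c1]] <- data.frame(state = s, tstart = t)
      hist[[c2]] <- data.frame(state = s, tstart = t)
      active <- c(setdiff(active, id), c1, c2)
      if (!is.null(sc$target_tips) && length(active) >= sc$target_tips) {
        # stop halfway to the next event so terminal branches are positive
        rates2 <- tot[state[active]]
        dt2 <- stats::rexp(1, sum(rates2))
        end_at(t + dt2 / 2)
        break
      }
    } else if (ev == 2) {
      t1[id] <- t; status[id] <- "dead"
      active <- setdiff(active, id)
      if (length(active) == 0) return(NULL)
    } else {
      w <- sc$q[s, ]; w[s] <- 0
      s2 <- sample.int(k, 1, prob = w)
      state[id] <- s2
      hist[[id]] <- rbind(hist[[id]], data.frame(state = s2, tstart = t))
    }
  }
  list(parent = parent[1:n_lin], t0 = t0[1:n_lin], t1 = t1[1:n_lin],
       state = state[1:n_lin], status = status[1:n_lin],
       hist = hist[1:n_lin], t_end = max(t1[1:n_lin]))
}

# prune extinct + unsampled lineages, merge unifurcations, build the phylo
sim_reconstruct <- function(sim, sc) {
  n <- length(sim$parent)
  extant <- which(sim$status == "extant")
  if (length(extant) < 2) return(NULL)
  keep <- extant[stats::runif(length(extant)) <= sc$rho[sim$state[extant]]]
  if (length(keep) < 2) return(NULL)
  if (!is.null(sc$target_tips)) {
    expected <- sc$target_tips * mean(sc$rho[sim$state[extant]])
    lo <- floor(expected * (1 - sc$tip_window))
    hi <- ceiling(expected * (1 + sc$tip_window))
    if (length(keep) < max(lo, 2) || length(keep) > hi) return(NULL)
  }
  children <- split(seq_len(n), sim$parent)
  surv <- logical(n)
  ord <- order(sim$t0, decreasing = TRUE)  # leaves first
  is_kept <- logical(n); is_kept[keep] <- TRUE
  for (id in ord) {
    kids <- children[[as.character(id)]]
    surv[id] <- is_kept[id] || (length(kids) > 0 && any(surv[kids]))
  }
  if (!any(surv)) return(NULL)
  # descend from the two root lineages; reconstructed root = first point
  # with two surviving sides
  roots <- which(sim$parent == 0L)
  surv_roots <- roots[surv[roots]]
  # chain(id): follow single-surviving-child runs, merging histories
  chain <- function(id) {
    segs <- list(hist_segments(sim, id))
    repeat {
      kids <- children[[as.character(id)]]
      sk <- kids[surv[kids]]
      if (length(sk) != 1) break
      id <- sk
      segs[[length(segs) + 1]] <- hist_segments(sim, id)
    }
    list(end = id, segs = coalesce_segments(do.call(rbind, segs)))
  }
  tip_ids <- integer(0); tip_states <- integer(0)
  edges <- list()  # each: parent_tmp, child_tmp, length, history
  node_states <- list()
  next_tmp <- 0L
  new_id <- function() { next_tmp <<- next_tmp + 1L; next_tmp }
  build <- function(start_id, parent_tmp) {
    ch <- chain(start_id)
    end <- ch$end
    kids <- children[[as.character(end)]]
    sk <- kids[surv[kids]]
    me <- new_id()
    if (length(sk) == 0) {
      tip_ids <<- c(tip_ids, me)
      tip_states <<- c(tip_states, sim$state[end])
    }
    node_states[[me]] <<- ch$segs$state[nrow(ch$segs)]
    if (!is.null(parent_tmp)) {
      edges[[length(edges) + 1]] <<- list(parent = parent_tmp, child = me,
                                          length = sum(ch$segs$duration),
                                          history = ch$segs)
    }
    for (s in sk) build(s, me)
    me
  }
  if (length(surv_roots) == 2) {
    root_tmp <- new_id()
    node_states[[root_tmp]] <- sim$state[roots[1]]
    for (r in surv_roots) build(r, root_tmp)
  } else {
    # one side extinct: reconstructed root lies within the surviving side;
    # drop the stem above the first bifurcation
    ch <- chain(surv_roots)
    end <- ch$end
    kids <- children[[as.character(end)]]
    sk <- kids[surv[kids]]
    if (length(sk) < 2) return(NULL)  # single kept tip
    root_tmp <- new_id()
    node_states[[root_tmp]] <- sim$state[end]
    for (s in sk) build(s, root_tmp)
  }
  n_tip <- length(tip_ids)
  if (n_tip < 2) return(NULL)
  # renumber: tips 1..n_tip, internals n_tip+1.., root first internal
  internal_tmp <- setdiff(seq_len(next_tmp), tip_ids)
  # root_tmp was created before its descendants; make it node n_tip + 1
  internal_tmp <- c(root_tmp, setdiff(internal_tmp, root_tmp))
  renum <- integer(next_tmp)
  renum[tip_ids] <- seq_len(n_tip)
  renum[internal_tmp] <- n_tip + seq_along(internal_tmp)
  edge <- t(vapply(edges, function(e) c(renum[e$parent], renum[e$child]),
                   numeric(2)))
  elen <- vapply(edges, `[[`, numeric(1), "length")
  tree <- structure(list(edge = matrix(as.integer(edge), ncol = 2),
                         edge.length = elen,
                         Nnode = length(internal_tmp),
                         tip.label = paste0("t", seq_len(n_tip))),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  histories <- lapply(edges, `[[`, "history")
  # histories are aligned with the original edge construction order; keep a
  # parallel index so reordering cannot desynchronize them
  key <- paste(renum[vapply(edges, `[[`, numeric(1), "parent")],
               renum[vapply(edges, `[[`, numeric(1), "child")])
  tree_key <- paste(tree$edge[, 1], tree$edge[, 2])
  histories <- histories[match(tree_key, key)]
  ns_vec <- integer(n_tip + length(internal_tmp))
  for (tmp in seq_len(next_tmp)) ns_vec[renum[tmp]] <- node_states[[tmp]]
  counts <- matrix(0L, sc$k, sc$k)
  for (h in histories) {
    st <- h$state
    if (length(st) > 1) {
      for (z in seq_len(length(st) - 1)) {
        counts[st[z], st[z + 1]] <- counts[st[z], st[z + 1]] + 1L
      }
    }
  }
  tip_obs <- stats::setNames(sc$obs_map[tip_states], tree$tip.label)
  list(tree = tree,
       tip_states = tip_obs,
       tip_state_idx = stats::setNames(tip_states, tree$tip.label),
       histories = histories, node_states = ns_vec,
       true_counts = counts)
}

# merge consecutive segments with identical state (arises when pruned
# unifurcation chains are concatenated)
coalesce_segments <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  run <- cumsum(c(TRUE, segs$state[-1] != segs$state[-nrow(segs)]))
  data.frame(state = segs$state[!duplicated(run)],
             duration = as.vector(tapply(segs$duration, run, sum)))
}

# segments (state, duration) of one lineage over its lifespan
hist_segments <- function(sim, id) {
  h <- sim$hist[[id]]
  tend <- sim$t1[id]
  dur <- c(diff(h$tstart), tend - h$tstart[nrow(h)])
  data.frame(state = h$state, duration = dur)
}

#' Simulate a discrete character on a tree under an Mk model
#'
#' Exact continuous-time simulation down every branch (exponential waiting
#' times between jumps), recording true node states and full branch
#' histories.
#'
#' @param tree A `"phylo"` tree.
#' @param spec An `"mk_spec"`.
#' @param rates Free-rate vector for the spec.
#' @param seed Integer seed.
#' @param root_state Starting state label; default drawn from the root
#'   prior implied by the spec (`stationary` for `fitzjohn`).
#' @return List with `tip_states` (named labels), `node_states`,
#'   `histories` (per-edge state/duration data.frames) and `true_counts`.
#' @export
simulate_mk_traits <- function(tree, spec, rates, seed = NULL,
                               root_state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- mk_Q(spec, rates)
  m <- spec$m
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  st <- integer(n_node)
  if (is.null(root_state)) {
    pr <- if (spec$root == "uniform") rep(1 / m, m) else mk_stationary(Q)
    st[n_tip + 1L] <- sample.int(m, 1, prob = pr)
  } else {
    st[n_tip + 1L] <- match(root_state, spec$states)
  }
  pre <- reorder_edges_preorder(tree)
  histories <- vector("list", nrow(tree$edge))
  counts <- matrix(0L, m, m, dimnames = dimnames(Q))
  for (k in pre) {
    a <- st[tree$edge[k, 1L]]
    tlen <- tree$edge.length[k]
    s <- a
    left <- tlen
    seg_state <- integer(0); seg_dur <- numeric(0)
    repeat {
      rate <- -Q[s, s]
      wait <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (wait >= left) {
        seg_state <- c(seg_state, s); seg_dur <- c(seg_dur, left)
        break
      }
      seg_state <- c(seg_state, s); seg_dur <- c(seg_dur, wait)
      left <- left - wait
      w <- Q[s, ]; w[s] <- 0
      s2 <- sample.int(m, 1, prob = w)
      counts[s, s2] <- counts[s, s2] + 1L
      s <- s2
    }
    histories[[k]] <- data.frame(state = seg_state, duration = seg_dur)
    st[tree$edge[k, 2L]] <- s
  }
  list(tip_states = stats::setNames(spec$states[st[seq_len(n_tip)]],
                                    tree$tip.label),
       node_states = spec$states[st], histories = histories,
       true_counts = counts)
}

#' Simulate a continuous trait with tunable phylogenetic signal
#'
#' Draws tip values from a multivariate normal with covariance
#' `sig2 * C(lambda)`, where `C` is the Brownian-motion covariance of the
#' tree and `lambda` scales its off-diagonal entries.
#'
#' @param tree A `"phylo"` tree.
#' @param sig2 Brownian rate (variance per my).
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param seed Integer seed.
#' @param mean Root (grand) mean.
#' @return Named numeric vector of tip values.
#' @export
simulate_continuous_traits <- function(tree, sig2 = 1, lambda = 1,
                                       seed = NULL, mean = 0) {
  stopifnot(sig2 > 0, lambda >= 0, lambda <= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- lambda_cov(ape::vcv.phylo(tree), lambda)
  L <- t(chol(C)) * sqrt(sig2)
  x <- mean + as.vector(L %*% stats::rnorm(nrow(C)))
  stats::setNames(x, tree$tip.label)
}

#' Write a versioned synthetic fixture suite
#'
#' Generates the canonical test inputs used across the package — small
#' hand-checkable trees, a 128-tip pure-birth tree with Mk and Brownian
#' traits, and a 300-tip state-dependent scenario (3 observed states, 2
#' hidden classes, constrained transitions, per-state sampling fractions
#' 0.72/0.68/0.76) — together with a JSON manifest of every file, its seed
#' and generating parameters. Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = 1L, seed = seed, files = list())
  put <- function(fname, lines, params) {
    writeLines(lines, file.path(out_dir, fname))
    manifest$files[[fname]] <<- params
  }
  put("tree2.nwk", "(A:1,B:1);", list(kind = "oracle", tips = 2))
  put("tree3.nwk", "((A:1,B:1):1,C:2);", list(kind = "oracle", tips = 3))
  put("tree4.nwk", "((A:1,B:1):1,(C:1,D:1):1);", list(kind = "oracle", tips = 4))
  put("tree6.nwk", "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);",
      list(kind = "oracle", tips = 6))
  yule <- sim_scenario("yule", lambda = 0.25, target_tips = 128)
  ty <- simulate_sse_tree(yule, seed = seed + 1)
  put("yule128.nwk", write_tree(ty$tree),
      list(kind = "yule", tips = length(ty$tree$tip.label),
           lambda = 0.25, seed = seed + 1))
  sse <- sim_scenario(
    "sse",
    lambda = rep(c(0.20, 0.28, 0.24), 2) / 1.25,
    mu = rep(c(0.20, 0.28, 0.24), 2) * 0.25 / 1.25,
    q = sse_scenario_q(0.03, 0.01),
    target_tips = 300,
    rho = rep(c(0.72, 0.68, 0.76), 2),
    obs_map = rep(c("01", "10", "11"), 2))
  ts <- simulate_sse_tree(sse, seed = seed + 2)
  put("sse300.nwk", write_tree(ts$tree),
      list(kind = "sse", tips = length(ts$tree$tip.label),
           hidden = 2, rho = c(0.72, 0.68, 0.76), seed = seed + 2,
           tip_state_counts = as.list(table(ts$tip_states))))
  df <- data.frame(species = names(ts$tip_states), code = ts$tip_states)
  utils::write.csv(df, file.path(out_dir, "sse300_states.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$files[["sse300_states.csv"]] <- list(kind = "sse_states",
                                                seed = seed + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Composite transition-rate matrix for the two-binary-character state space
#'
#' Helper building the 6x6 (3 observed x 2 hidden) generator used by
#' simulation scenarios: observed moves through the intermediate code at
#' rate `q_obs`, hidden-class flips at rate `q_hidden`, extremes never
#' interconvert directly.
#'
#' @param q_obs Observed-state transition rate (to/from the intermediate).
#' @param q_hidden Hidden-class transition rate.
#' @return A 6x6 rate matrix (diagonal zero).
#' @export
sse_scenario_q <- function(q_obs = 0.03, q_hidden = 0.01) {
  q <- matrix(0, 6, 6)
  obs <- rep(1:3, 2)   # 1 = "01", 2 = "10", 3 = "11"
  hid <- rep(1:2, each = 3)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    if (hid[i] == hid[j] && (obs[i] == 3 || obs[j] == 3)) q[i, j] <- q_obs
    if (obs[i] == obs[j] && hid[i] != hid[j]) q[i, j] <- q_hidden
  }
  q
}
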