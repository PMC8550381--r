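#' Construct a multistate hidden-state SSE model specification
#'
#' Low-level constructor for a speciation-extinction model over composite
#' states (observed binary-pair code x hidden class). Diversification is
#' parameterized as turnover `tau = lambda + mu` and extinction fraction
#' `eps = mu / lambda`, the reparameterization that behaves better than raw
#' speciation/extinction when the two are correlated. Sharing maps assign
#' each composite state's tau and eps, and each allowed transition cell, to
#' a free-parameter index; masked transition cells are structural zeros.
#'
#' @param name Model name.
#' @param description One-line description.
#' @param obs_states Observed binary-pair codes, default `c("01","10","11")`.
#' @param hidden Number of hidden classes (1-3).
#' @param tau_map,eps_map Integer vectors (length = number of composite
#'   states) giving the free-parameter index of each composite state's
#'   turnover / extinction fraction.
#' @param q_map Integer matrix (composite x composite); 0 = structural zero,
#'   positive entries index free transition rates.
#' @param rho Named sampling fractions per observed state.
#' @param root Root state treatment, `"fitzjohn"` or `"uniform"`.
#' @return An object of class `"sse_spec"`.
#' @export
sse_spec <- function(name, description = name, obs_states = c("01", "10", "11"),
                     hidden = 1, tau_map, eps_map, q_map,
                     rho = NULL, root = c("fitzjohn", "uniform")) {
  root <- match.arg(root)
  n_obs <- length(obs_states)
  ns <- n_obs * hidden
  hidden_labels <- LETTERS[seq_len(hidden)]
  comp <- as.vector(outer(obs_states, hidden_labels, paste0))
  stopifnot(length(tau_map) == ns, length(eps_map) == ns,
            all(dim(q_map) == c(ns, ns)))
  if (is.null(rho)) rho <- stats::setNames(rep(1, n_obs), obs_states)
  stopifnot(all(obs_states %in% names(rho)), all(rho > 0), all(rho <= 1))
  n_tau <- max(tau_map)
  n_eps <- max(eps_map)
  n_q <- max(q_map, 0)
  structure(list(name = name, description = description,
                 obs_states = obs_states, hidden = hidden,
                 hidden_labels = hidden_labels, comp_states = comp,
                 comp_obs = rep(obs_states, times = hidden), ns = ns,
                 tau_map = tau_map, eps_map = eps_map, q_map = q_map,
                 rho = rho[obs_states], root = root,
                 n_tau = n_tau, n_eps = n_eps, n_q = n_q,
                 n_free = n_tau + n_eps + n_q),
            class = "sse_spec")
}

#' @export
print.sse_spec <- function(x, ...) {
  cat("SSE model '", x$name, "': ", x$description, "\n", sep = "")
  cat(" ", length(x$obs_states), "observed states x", x$hidden,
      "hidden class(es);", x$n_free, "free parameters (",
      x$n_tau, "turnover,", x$n_eps, "extinction-fraction,", x$n_q,
      "transition )\n")
  invisible(x)
}

# expand a packed free-parameter vector (tau..., eps..., q...) into
# per-composite lambda, mu and the composite Q matrix
sse_expand <- function(spec, par) {
  stopifnot(length(par) == spec$n_free)
  tau <- par[seq_len(spec$n_tau)][spec$tau_map]
  eps <- par[spec$n_tau + seq_len(spec$n_eps)][spec$eps_map]
  qfree <- par[spec$n_tau + spec$n_eps + seq_len(spec$n_q)]
  Q <- matrix(0, spec$ns, spec$ns,
              dimnames = list(spec$comp_states, spec$comp_states))
  pos <- spec$q_map > 0
  Q[pos] <- qfree[spec$q_map[pos]]
  lambda <- tau / (1 + eps)
  mu <- tau * eps / (1 + eps)
  list(tau = tau, eps = eps, lambda = lambda, mu = mu, Q = Q)
}

# default transition sharing for the binary-pair composite space:
# observed moves 01<->11 and 10<->11 (one free rate per ordered pair,
# shared across hidden classes), hidden moves within an observed state
# (n_hidden_rates = 1 shared, or 2 directional for H = 2)
sse_default_qmap <- function(obs_states, hidden, absorbing = NULL,
                             hidden_rates = 1) {
  n_obs <- length(obs_states)
  ns <- n_obs * hidden
  comp_obs <- rep(seq_len(n_obs), times = hidden)
  comp_hid <- rep(seq_len(hidden), each = n_obs)
  q_map <- matrix(0L, ns, ns)
  # observed moves: anything <-> the intermediate "11"
  mid <- which(obs_states == "11")
  stopifnot(length(mid) == 1)
  pairs <- list()
  for (o in setdiff(seq_len(n_obs), mid)) {
    pairs[[length(pairs) + 1]] <- c(o, mid)
    pairs[[length(pairs) + 1]] <- c(mid, o)
  }
  next_idx <- 0L
  for (pr in pairs) {
    if (!is.null(absorbing) && obs_states[pr[1]] == absorbing) next
    next_idx <- next_idx + 1L
    for (h in seq_len(hidden)) {
      i <- which(comp_obs == pr[1] & comp_hid == h)
      j <- which(comp_obs == pr[2] & comp_hid == h)
      q_map[i, j] <- next_idx
    }
  }
  # hidden moves: same observed state, different hidden class
  if (hidden > 1) {
    if (hidden_rates == 1) {
      next_idx <- next_idx + 1L
      for (i in seq_len(ns)) for (j in seq_len(ns)) {
        if (comp_obs[i] == comp_obs[j] && comp_hid[i] != comp_hid[j]) {
          q_map[i, j] <- next_idx
        }
      }
    } else {
      stopifnot(hidden == 2)
      up <- next_idx + 1L
      dn <- next_idx + 2L
      next_idx <- next_idx + 2L
      for (i in seq_len(ns)) for (j in seq_len(ns)) {
        if (comp_obs[i] == comp_obs[j] && comp_hid[i] != comp_hid[j]) {
          q_map[i, j] <- if (comp_hid[i] < comp_hid[j]) up else dn
        }
      }
    }
  }
  q_map
}

#' Build the eight-model SSE set for a trait
#'
#' Returns the model set used to test state-dependent diversification for a
#' three-state character coded as two binary characters (`01`/`10`/`11`,
#' `00` unobserved): an equal-rates null ("Dull"), state-dependent
#' diversification without (MuSSE) and with a hidden class (MuHiSSE, plus a
#' "Relaxed" variant freeing the second hidden-class transition rate), two
#' absorbing models in which one extreme state cannot be left, and
#' character-independent (CID) models in which diversification varies only
#' across 2 or 3 hidden classes. All models share the constrained observed
#' transition structure: direct moves between the two extreme codes are
#' structural zeros, so every path passes through the intermediate `11`.
#'
#' @param trait `"size"` (small `01`, large `10`, medium `11`) or
#'   `"ecotype"` (benthic `01`, pelagic `10`, intermediate `11`).
#' @param rho Named sampling fractions per observed code; defaults follow
#'   the per-ecotype sampling of the motivating dataset (benthic 0.72,
#'   pelagic 0.68, intermediate 0.76), reused for size classes.
#' @param root Root treatment for all models.
#' @return Named list of eight `"sse_spec"` objects.
#' @export
build_model_set <- function(trait = c("size", "ecotype"), rho = NULL,
                            root = "fitzjohn") {
  trait <- match.arg(trait)
  obs <- c("01", "10", "11")
  labels <- if (trait == "size") {
    c("01" = "small", "10" = "large", "11" = "medium")
  } else {
    c("01" = "benthic", "10" = "pelagic", "11" = "intermediate")
  }
  if (is.null(rho)) rho <- c("01" = 0.72, "10" = 0.68, "11" = 0.76)
  mk <- function(name, description, hidden, tau_map, eps_map, q_map) {
    sse_spec(name, description, obs, hidden, tau_map, eps_map, q_map,
             rho = rho, root = root)
  }
  per_comp <- function(h) seq_len(3 * h)               # free per composite
  per_obs <- function(h) rep(seq_len(3), times = h)    # shared over hidden
  per_hidden <- function(h) rep(seq_len(h), each = 3)  # CID structure
  shared <- function(h) rep(1L, 3 * h)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  abs1 <- labels[["10"]]  # large / pelagic extreme
  abs2 <- labels[["01"]]  # small / benthic extreme
  set <- list(
    mk("Dull", "Equal rates", 1, shared(1), shared(1),
       sse_default_qmap(obs, 1)),
    mk("MuSSE", "State dependent diversification", 1,
       per_obs(1), per_obs(1), sse_default_qmap(obs, 1)),
    mk("MuHiSSE", "State dependent diversification with a hidden state", 2,
       per_comp(2), per_comp(2), sse_default_qmap(obs, 2)),
    mk("MuHiSSE Relaxed",
       "Relaxed state dependent diversification with a hidden state", 2,
       per_comp(2), per_comp(2), sse_default_qmap(obs, 2, hidden_rates = 2)),
    mk(paste(cap(abs1), "Absorbing"),
       paste("No transitions out of", abs1, "state"), 2,
       per_comp(2), per_comp(2), sse_default_qmap(obs, 2, absorbing = "10")),
    mk(paste(cap(abs2), "Absorbing"),
       paste("No transitions out of", abs2, "state"), 2,
       per_comp(2), per_comp(2), sse_default_qmap(obs, 2, absorbing = "01")),
    mk("CID2", "Character-independent with 2 hidden states", 2,
       per_hidden(2), per_hidden(2), sse_default_qmap(obs, 2)),
    mk("CID3", "Character-independent with 3 hidden states", 3,
       per_hidden(3), per_hidden(3), sse_default_qmap(obs, 3))
  )
  names(set) <- vapply(set, `[[`, character(1), "name")
  set
}

sse_tip_init <- function(tree, tip_codes, spec) {
  codes <- tip_codes[tree$tip.label]
  if (anyNA(codes)) {
    stop("tip codes missing for: ",
         paste(utils::head(tree$tip.label[is.na(codes)], 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(codes %in% spec$obs_states)
  if (any(bad)) stop("invalid tip codes (expected 01/10/11): ",
                     paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  n <- length(codes)
  tipD <- matrix(0, n, spec$ns)
  rho_comp <- spec$rho[spec$comp_obs]
  for (i in seq_len(n)) {
    match_i <- spec$comp_obs == codes[i]
    tipD[i, match_i] <- rho_comp[match_i]
  }
  list(tipD = tipD, tipE = 1 - rho_comp)
}

sse_backbone <- function(tree, tip_codes, spec, pars, force_node = 0L,
                         force_mask = NULL, atol = 1e-10, rtol = 1e-8) {
  init <- sse_tip_init(tree, tip_codes, spec)
  po <- reorder_edges_postorder(tree)
  if (is.null(force_mask)) force_mask <- rep(1, spec$ns)
  sse_postorder_cpp(tree$edge, tree$edge.length, po,
                    length(tree$tip.label),
                    length(tree$tip.label) + tree$Nnode,
                    init$tipD, init$tipE, pars$lambda, pars$mu, pars$Q,
                    as.integer(force_node), force_mask, atol, rtol)
}

sse_root_loglik <- function(res, pars, root = "fitzjohn",
                            condition_on_survival = TRUE) {
  if (!res$ok) {
    if (is.infinite(res$logscale)) return(-Inf)
    stop("SSE integration failed (stiff branch); check parameter bounds",
         call. = FALSE)
  }
  D <- res$rootD
  E <- res$rootE
  w <- if (root == "uniform") rep(1 / length(D), length(D)) else D / sum(D)
  dens <- if (condition_on_survival) {
    D / (pars$lambda * (1 - E)^2)
  } else {
    D
  }
  log(sum(w * dens)) + res$logscale
}

#' SSE model log-likelihood
#'
#' Likelihood of observed tip codes under a multistate (hidden-state)
#' speciation-extinction model, by backward-in-time integration of the
#' extinction and data probabilities along every branch, combination at
#' nodes, and root weighting with conditioning on the survival of both root
#' lineages. Tips enter with their per-state sampling fraction.
#'
#' @param tree Ultrametric `"phylo"` tree.
#' @param tip_codes Named vector of binary-pair codes (`"01"/"10"/"11"`).
#' @param spec An `"sse_spec"`.
#' @param par Free-parameter vector `c(tau..., eps..., q...)` on the natural
#'   scale, or a list with elements `lambda`, `mu`, `Q` (per composite
#'   state).
#' @param condition_on_survival Condition on both root lineages surviving.
#' @param atol,rtol Absolute/relative integration tolerances.
#' @return Log-likelihood (numeric scalar; `-Inf` for impossible data).
#' @export
sse_loglik <- function(tree, tip_codes, spec, par,
                       condition_on_survival = TRUE,
                       atol = 1e-10, rtol = 1e-8) {
  stopifnot_ultrametric(tree, what = "the SSE likelihood")
  pars <- if (is.list(par)) par else sse_expand(spec, par)
  res <- sse_backbone(tree, tip_codes, spec, pars, atol = atol, rtol = rtol)
  sse_root_loglik(res, pars, root = spec$root,
                  condition_on_survival = condition_on_survival)
}

sse_bounds <- function(spec) {
  list(lower = c(rep(1e-4, spec$n_tau), rep(1e-6, spec$n_eps),
                 rep(1e-6, spec$n_q)),
       upper = c(rep(10, spec$n_tau), rep(3, spec$n_eps),
                 rep(1, spec$n_q)))
}

#' Fit an SSE model by multi-start maximum likelihood
#'
#' Box-constrained optimization over log-transformed turnover, extinction
#' fraction and transition rates, repeated from `n_starts` random
#' log-uniform initializations (plus one deterministic heuristic start) to
#' guard against local optima; the best optimum is retained.
#'
#' @inheritParams sse_loglik
#' @param n_starts Number of starting points.
#' @param seed Integer seed making the random starts reproducible.
#' @return Object of class `"sse_fit"`: `model`, `description`, `loglik`,
#'   `k`, `AIC`, `AICc`, `par` (packed free parameters), `pars` (expanded
#'   lambda/mu/Q), `spec`, `starts` (per-start log-likelihoods).
#' @export
fit_sse <- function(tree, tip_codes, spec, n_starts = 25, seed = NULL,
                    atol = 1e-8, rtol = 1e-7) {
  stopifnot(n_starts >= 1)
  stopifnot_ultrametric(tree, what = "SSE fitting")
  if (!is.null(seed)) set.seed(seed)
  b <- sse_bounds(spec)
  init <- sse_tip_init(tree, tip_codes, spec)
  po <- reorder_edges_postorder(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  negll <- function(logp) {
    pars <- sse_expand(spec, exp(logp))
    res <- sse_postorder_cpp(tree$edge, tree$edge.length, po, n_tip, n_node,
                             init$tipD, init$tipE, pars$lambda, pars$mu,
                             pars$Q, 0L, rep(1, spec$ns), atol, rtol)
    ll <- tryCatch(sse_root_loglik(res, pars, root = spec$root),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  depth <- max(node_depths(tree)[seq_len(n_tip)])
  tau0 <- max(log(n_tip / 2) / depth, 2 * b$lower[1])
  heur <- c(rep(tau0, spec$n_tau), rep(0.5, spec$n_eps),
            rep(0.1 / depth, spec$n_q))
  heur <- pmin(pmax(heur, b$lower * 1.01), b$upper * 0.99)
  starts <- list(log(heur))
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- stats::runif(spec$n_free, log(b$lower), log(b$upper))
    }
  }
  best <- NULL
  start_ll <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], negll, method = "L-BFGS-B",
                   lower = log(b$lower), upper = log(b$upper),
                   control = list(maxit = 400, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit) || fit$value >= 1e10) next
    start_ll[i] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all ", length(starts), " optimization starts failed for model '",
         spec$name, "'", call. = FALSE)
  }
  par <- exp(best$par)
  ll <- -best$value
  k <- spec$n_free
  structure(list(model = spec$name, description = spec$description,
                 loglik = ll, k = k, AIC = 2 * k - 2 * ll,
                 AICc = 2 * k - 2 * ll +
                   2 * k * (k + 1) / max(n_tip - k - 1, 1),
                 par = par, pars = sse_expand(spec, par), spec = spec,
                 starts = start_ll, convergence = best$convergence),
            class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat("SSE fit '", x$model, "': lnL = ", format(x$loglik, digits = 7),
      ", k = ", x$k, ", AIC = ", format(x$AIC, digits = 7), "\n", sep = "")
  invisible(x)
}

#' Rank a set of model fits by AIC with Akaike weights
#'
#' Computes `delta_AIC = AIC - min(AIC)` and the Akaike weights
#' `w = exp(-delta/2) / sum(exp(-delta/2))`, ordered by decreasing weight.
#' Accepts either a list of `"sse_fit"` (or any objects with `AIC`,
#' `loglik`, `k` fields) or a bare named numeric vector of AIC values.
#'
#' @param fits List of fits, or numeric AIC vector (optionally named).
#' @param criterion `"AIC"` (headline) or `"AICc"`.
#' @return A data.frame with columns
#'   `model,description,free_parameters,lnL,AIC,AICc,delta_AIC,weight`,
#'   sorted by decreasing weight.
#' @examples
#' rank_models(c(m1 = 100.0, m2 = 101.2, m3 = 110.0))
#' @export
rank_models <- function(fits, criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  if (is.numeric(fits)) {
    nm <- if (is.null(names(fits))) paste0("model", seq_along(fits))
          else names(fits)
    tab <- data.frame(model = nm, description = NA_character_,
                      free_parameters = NA_integer_, lnL = NA_real_,
                      AIC = as.numeric(fits), AICc = as.numeric(fits),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      model = vapply(fits, `[[`, character(1), "model"),
      description = vapply(fits, `[[`, character(1), "description"),
      free_parameters = vapply(fits, `[[`, numeric(1), "k"),
      lnL = vapply(fits, `[[`, numeric(1), "loglik"),
      AIC = vapply(fits, `[[`, numeric(1), "AIC"),
      AICc = vapply(fits, `[[`, numeric(1), "AICc"),
      stringsAsFactors = FALSE)
  }
  score <- tab[[criterion]]
  tab$delta_AIC <- score - min(score)
  w <- exp(-tab$delta_AIC / 2)
  tab$weight <- w / sum(w)
  tab <- tab[order(-tab$weight, tab$delta_AIC), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Marginal ancestral reconstruction under a fitted SSE model
#'
#' For each node and composite state, the marginal probability is obtained
#' by recomputing the likelihood with the node's state restricted and
#' normalizing across states — the conditional-likelihood form of the
#' re-rooted marginal. Observed-state marginals sum the composite marginals
#' over hidden classes.
#'
#' @inheritParams sse_loglik
#' @param nodes Node numbers to reconstruct (default all internal nodes).
#' @return List with `composite` (nodes x composite states matrix of
#'   marginals) and `observed` (nodes x observed states).
#' @export
marginal_reconstruction_sse <- function(tree, tip_codes, spec, par,
                                        nodes = NULL,
                                        atol = 1e-9, rtol = 1e-8) {
  pars <- if (is.list(par)) par else sse_expand(spec, par)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(nodes)) nodes <- (n_tip + 1L):n_node
  comp <- matrix(NA_real_, length(nodes), spec$ns,
                 dimnames = list(node_names(tree, nodes), spec$comp_states))
  for (r in seq_along(nodes)) {
    lls <- vapply(seq_len(spec$ns), function(i) {
      mask <- rep(0, spec$ns)
      mask[i] <- 1
      res <- sse_backbone(tree, tip_codes, spec, pars,
                          force_node = nodes[r], force_mask = mask,
                          atol = atol, rtol = rtol)
      tryCatch(sse_root_loglik(res, pars, root = spec$root),
               error = function(e) -Inf)
    }, numeric(1))
    mx <- max(lls)
    p <- if (is.finite(mx)) exp(lls - mx) else rep(0, spec$ns)
    comp[r, ] <- p / sum(p)
  }
  obs <- t(apply(comp, 1, function(row) {
    tapply(row, spec$comp_obs, sum)[spec$obs_states]
  }))
  colnames(obs) <- spec$obs_states
  list(composite = comp, observed = obs, nodes = nodes)
}

node_names <- function(tree, nodes) {
  n_tip <- length(tree$tip.label)
  ifelse(nodes <= n_tip, tree$tip.label[pmin(nodes, n_tip)],
         paste0("node", nodes))
}

#' Model-averaged diversification rates
#'
#' Averages per-node diversification quantities over a fitted model set
#' using Akaike weights: for node `v`,
#' `rate(v) = sum_m w_m sum_i P_m(state i at v) rate_{m,i}`. Net
#' diversification is `lambda - mu`, turnover `lambda + mu`, and the
#' transition rate of a state its total outflow `sum_j q_ij`.
#'
#' @param fits List of `"sse_fit"` objects.
#' @param reconstructions List of [marginal_reconstruction_sse()] results
#'   aligned with `fits` (same nodes in each).
#' @param min_weight Models below this Akaike weight may omit a
#'   reconstruction; a missing reconstruction above it is an error.
#' @param criterion Ranking criterion for the weights.
#' @return A data.frame per node: `node`, `net_div`, `turnover`,
#'   `speciation`, `extinction`, `transition`.
#' @export
model_average_rates <- function(fits, reconstructions,
                                min_weight = 0.01,
                                criterion = "AIC") {
  stopifnot(length(fits) >= 1, length(reconstructions) == length(fits))
  tab <- rank_models(fits, criterion)
  w <- tab$weight[match(vapply(fits, `[[`, character(1), "model"),
                        tab$model)]
  have <- !vapply(reconstructions, is.null, logical(1))
  if (any(w > min_weight & !have)) {
    stop("missing reconstruction for model(s) with weight > ", min_weight,
         ": ", paste(tab$model[w > min_weight & !have], collapse = ", "),
         call. = FALSE)
  }
  idx <- which(have)
  w_used <- w[idx] / sum(w[idx])
  nodes <- reconstructions[[idx[1]]]$nodes
  acc <- matrix(0, length(nodes), 5,
                dimnames = list(NULL, c("net_div", "turnover", "speciation",
                                        "extinction", "transition")))
  for (z in seq_along(idx)) {
    f <- fits[[idx[z]]]
    rec <- reconstructions[[idx[z]]]
    stopifnot(identical(rec$nodes, nodes))
    p <- f$pars
    out_q <- rowSums(p$Q)
    per_state <- cbind(p$lambda - p$mu, p$lambda + p$mu, p$lambda, p$mu,
                       out_q)
    acc <- acc + w_used[z] * (rec$composite %*% per_state)
  }
  data.frame(node = nodes, acc, check.names = FALSE)
}
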