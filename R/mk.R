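#' Build an Mk transition-rate model specification
#'
#' Constructs the parameter-sharing structure of a continuous-time Markov
#' model for a discrete character: equal rates (ER, one shared rate),
#' symmetric (SYM, one rate per unordered pair) or all rates different (ARD).
#' With `constrained = TRUE` the two extreme states of an ordered three-state
#' alphabet (small/large, benthic/pelagic) cannot interconvert directly:
#' their cells are structural zeros and every path passes through the
#' intermediate state.
#'
#' @param alphabet Character vector of state labels (size `m >= 2`). For
#'   constrained models the alphabet must contain a designated intermediate
#'   (`"M"`, `"I"` or `"intermediate"`).
#' @param model One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param constrained Logical; mask direct extreme-to-extreme transitions.
#' @param root Root state treatment used by likelihood computations:
#'   `"fitzjohn"` (state weights proportional to their likelihood share),
#'   `"uniform"`, or `"stationary"`.
#' @return An object of class `"mk_spec"`: `states`, `m`, `model`,
#'   `constrained`, `root`, `index` (an `m x m` integer matrix; 0 marks the
#'   diagonal and structural zeros, positive entries give the free-parameter
#'   index of each allowed cell) and `n_free`.
#' @examples
#' build_rate_matrix(c("S", "M", "L"), "ARD", constrained = TRUE)$n_free  # 4
#' @export
build_rate_matrix <- function(alphabet, model = c("ER", "SYM", "ARD"),
                              constrained = FALSE,
                              root = c("fitzjohn", "uniform", "stationary")) {
  model <- match.arg(model)
  root <- match.arg(root)
  m <- length(alphabet)
  if (m < 2) stop("alphabet needs at least 2 states", call. = FALSE)
  if (anyDuplicated(alphabet)) stop("duplicate state labels", call. = FALSE)
  allowed <- matrix(TRUE, m, m, dimnames = list(alphabet, alphabet))
  diag(allowed) <- FALSE
  if (constrained) {
    mid <- intersect(alphabet, c("M", "I", "intermediate"))
    if (length(mid) != 1 || m != 3) {
      stop("constrained models need a 3-state alphabet with a designated ",
           "intermediate state (M / I / intermediate)", call. = FALSE)
    }
    ext <- setdiff(alphabet, mid)
    allowed[ext[1], ext[2]] <- FALSE
    allowed[ext[2], ext[1]] <- FALSE
  }
  index <- matrix(0L, m, m, dimnames = list(alphabet, alphabet))
  if (model == "ER") {
    index[allowed] <- 1L
  } else if (model == "SYM") {
    k <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (allowed[i, j]) {
        k <- k + 1L
        index[i, j] <- k
        index[j, i] <- k
      }
    }
  } else {
    k <- 0L
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (allowed[i, j]) {
        k <- k + 1L
        index[i, j] <- k
      }
    }
  }
  structure(list(states = alphabet, m = m, model = model,
                 constrained = constrained, root = root, index = index,
                 n_free = max(index)),
            class = "mk_spec")
}

#' @export
print.mk_spec <- function(x, ...) {
  cat("Mk model:", x$model, if (x$constrained) "(constrained)", "on",
      x$m, "states;", x$n_free, "free rate(s); root:", x$root, "\n")
  print(x$index)
  invisible(x)
}

# instantiate Q (rows sum to zero) from a spec and free rates
mk_Q <- function(spec, rates) {
  if (length(rates) != spec$n_free) {
    stop("expected ", spec$n_free, " rates, got ", length(rates),
         call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  Q <- matrix(0, spec$m, spec$m, dimnames = dimnames(spec$index))
  pos <- spec$index > 0
  Q[pos] <- rates[spec$index[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

# matrix exponential by scaling and squaring with a Taylor core; m <= 8,
# and Q may be defective under structural-zero masks so no eigendecomposition
mat_exp <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  As <- A / 2^s
  m <- nrow(A)
  E <- diag(m) + As
  term <- As
  for (k in 2:16) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# stationary distribution of Q (pi Q = 0, sum(pi) = 1); minimum-norm least
# squares via SVD so masked/defective/near-zero structures are handled
# (a vanishing generator has no unique stationary law; uniform is returned)
mk_stationary <- function(Q) {
  m <- nrow(Q)
  if (max(abs(Q)) < 1e-12) return(rep(1 / m, m))
  A <- rbind(t(Q), rep(1, m))
  b <- c(rep(0, m), 1)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  pi <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  pi <- pmax(as.vector(pi), 0)
  pi / sum(pi)
}

# build tip partial-likelihood matrix from a named state vector; NA (or
# states listed in `ambiguous`) become all-ones rows
mk_tip_partials <- function(tree, tip_states, states) {
  n <- length(tree$tip.label)
  L <- matrix(0, n, length(states), dimnames = list(tree$tip.label, states))
  x <- tip_states[tree$tip.label]
  if (anyNA(names(tip_states)) || any(!(tree$tip.label %in% names(tip_states)))) {
    missing_sp <- setdiff(tree$tip.label, names(tip_states))
    if (length(missing_sp)) {
      stop("tip states missing for: ", paste(utils::head(missing_sp, 5),
                                             collapse = ", "), call. = FALSE)
    }
  }
  for (i in seq_len(n)) {
    if (is.na(x[i])) {
      L[i, ] <- 1
    } else {
      if (!(x[i] %in% states)) {
        stop("tip ", tree$tip.label[i], " has state '", x[i],
             "' outside the alphabet", call. = FALSE)
      }
      L[i, x[i]] <- 1
    }
  }
  L
}

# Felsenstein pruning; returns log-likelihood plus per-node partials and
# cached per-edge transition matrices for reuse by ASR / stochastic mapping
mk_pruning <- function(tree, tipL, Q, root = "fitzjohn", root_prior = NULL) {
  n_tip <- nrow(tipL)
  m <- ncol(Q)
  n_node <- n_tip + tree$Nnode
  down <- matrix(0, n_node, m)
  down[seq_len(n_tip), ] <- tipL
  logscale <- 0
  root_node <- n_tip + 1L
  po <- reorder_edges_postorder(tree)
  P <- vector("list", nrow(tree$edge))
  contrib <- matrix(1, n_node, m)  # running product over children at a parent
  done_children <- integer(n_node)
  n_children <- tabulate(tree$edge[, 1L], nbins = n_node)
  for (k in po) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    P[[k]] <- mat_exp(Q * tree$edge.length[k])
    v <- as.vector(P[[k]] %*% down[ch, ])
    contrib[p, ] <- contrib[p, ] * v
    done_children[p] <- done_children[p] + 1L
    if (done_children[p] == n_children[p]) {
      s <- sum(contrib[p, ])
      if (s <= 0 || !is.finite(s)) {
        stop("numerical underflow in pruning at node ", p, call. = FALSE)
      }
      down[p, ] <- contrib[p, ] / s
      logscale <- logscale + log(s)
    }
  }
  pr <- mk_root_prior(down[root_node, ], Q, root, root_prior)
  lik <- sum(pr * down[root_node, ])
  list(loglik = log(lik) + logscale, down = down, P = P,
       root_prior = pr, logscale = logscale)
}

mk_root_prior <- function(droot, Q, root, root_prior = NULL) {
  m <- length(droot)
  if (!is.null(root_prior)) return(root_prior / sum(root_prior))
  switch(root,
         uniform = rep(1 / m, m),
         stationary = mk_stationary(Q),
         fitzjohn = droot / sum(droot),
         stop("unknown root treatment: ", root, call. = FALSE))
}

#' Mk model log-likelihood
#'
#' Felsenstein pruning likelihood of discrete tip states under a
#' continuous-time Markov model, with per-branch transition probabilities
#' `expm(Q t)` and the root handled according to the spec's root treatment.
#' Missing (`NA`) tip states are treated as fully ambiguous.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param tip_states Named character vector of tip states (names = tip
#'   labels); `NA` allowed.
#' @param spec An `"mk_spec"` from [build_rate_matrix()].
#' @param rates Non-negative vector of free rates, length `spec$n_free`.
#' @param root Override of the spec's root treatment.
#' @return The log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_states, spec, rates, root = spec$root) {
  Q <- mk_Q(spec, rates)
  tipL <- mk_tip_partials(tree, tip_states, spec$states)
  mk_pruning(tree, tipL, Q, root = root)$loglik
}

#' Maximum-likelihood fit of an Mk model
#'
#' Maximizes the pruning likelihood over the free transition rates by
#' box-constrained quasi-Newton optimization in log-rate space, with random
#' multi-starts drawn log-uniformly within the bounds.
#'
#' @inheritParams mk_loglik
#' @param n_starts Number of random starting points (the first start is a
#'   deterministic heuristic based on the tree depth).
#' @param seed Integer seed for the random starts.
#' @param bounds Rate bounds (per unit branch length), default `[1e-9, 1e3]`.
#' @return An object of class `"mk_fit"`: `rates`, `loglik`, `k` (free
#'   parameters), `AIC`, `AICc`, `spec`, `starts` (per-start log-likelihoods).
#' @export
fit_mk <- function(tree, tip_states, spec, n_starts = 10, seed = NULL,
                   bounds = c(1e-9, 1e3)) {
  obs <- unique(tip_states[!is.na(tip_states)])
  if (length(obs) < 2) {
    warning("only one observed state; rate estimate lies on the boundary")
  }
  tipL <- mk_tip_partials(tree, tip_states, spec$states)
  negll <- function(logr) {
    Q <- mk_Q(spec, exp(logr))
    -mk_pruning(tree, tipL, Q, root = spec$root)$loglik
  }
  if (!is.null(seed)) set.seed(seed)
  depth <- max(node_depths(tree)[seq_along(tree$tip.label)])
  lo <- log(bounds[1]); hi <- log(bounds[2])
  starts <- list(rep(log(1 / depth), spec$n_free))
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- stats::runif(spec$n_free, log(1e-4), log(10 / depth))
    }
  }
  best <- NULL
  start_ll <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], negll, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) { start_ll[i] <- NA_real_; next }
    start_ll[i] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  k <- spec$n_free
  n <- length(tree$tip.label)
  ll <- -best$value
  structure(list(rates = exp(best$par), loglik = ll, k = k,
                 AIC = 2 * k - 2 * ll,
                 AICc = 2 * k - 2 * ll + 2 * k * (k + 1) / max(n - k - 1, 1),
                 Q = mk_Q(spec, exp(best$par)),
                 spec = spec, starts = start_ll,
                 convergence = best$convergence),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk", x$spec$model, if (x$spec$constrained) "(constrained)",
      "fit: lnL =", format(x$loglik, digits = 6), "k =", x$k,
      "AIC =", format(x$AIC, digits = 6), "\n")
  cat("rates:", paste(format(x$rates, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
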