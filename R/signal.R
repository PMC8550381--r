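match_tip_values <- function(tree, x, what = "trait") {
  if (is.null(names(x))) stop(what, " vector must be named by tip label",
                              call. = FALSE)
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop(what, " missing for tips: ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  x[tree$tip.label]
}

bm_profile <- function(C_chol, x) {
  # profile ML of the phylogenetic mean and rate given chol(C); returns
  # loglik, ahat, sig2
  n <- length(x)
  one <- rep(1, n)
  z1 <- backsolve(C_chol, one, transpose = TRUE)
  zx <- backsolve(C_chol, x, transpose = TRUE)
  ahat <- sum(z1 * zx) / sum(z1 * z1)
  r <- zx - ahat * z1
  sig2 <- sum(r * r) / n
  logdet <- 2 * sum(log(diag(C_chol)))
  ll <- -0.5 * (n * log(2 * pi * sig2) + logdet + n)
  list(loglik = ll, ahat = ahat, sig2 = sig2)
}

#' Blomberg's K for a continuous trait
#'
#' K compares the observed ratio of the ordinary mean squared error around
#' the phylogenetic mean to the phylogenetically corrected mean squared
#' error, against the expectation of that ratio under Brownian motion on the
#' same tree; K near 1 matches Brownian motion, K < 1 means less signal.
#' The permutation p-value shuffles tip labels and asks how often the
#' phylogenetically corrected error variance is as small as observed (with a
#' `+1` continuity correction).
#'
#' @param tree A `"phylo"` tree.
#' @param x Named numeric vector of tip values (no missing values).
#' @param n_rand Number of tip-label randomizations for the p-value.
#' @param seed Integer seed.
#' @return A list of class `"signal_result"` with `statistic = "BlombergK"`,
#'   `estimate`, `p_value` and `n_rand`.
#' @export
blomberg_k <- function(tree, x, n_rand = 1000, seed = NULL) {
  x <- match_tip_values(tree, x)
  n <- length(x)
  if (n < 4) stop("Blomberg's K needs at least 4 tips", call. = FALSE)
  if (stats::sd(x) == 0) stop("K is undefined for a constant trait",
                              call. = FALSE)
  C <- ape::vcv.phylo(tree)
  Ch <- chol(C)
  k_parts <- function(v) {
    one <- rep(1, n)
    z1 <- backsolve(Ch, one, transpose = TRUE)
    zv <- backsolve(Ch, v, transpose = TRUE)
    ahat <- sum(z1 * zv) / sum(z1 * z1)
    mse0 <- sum((v - ahat)^2) / (n - 1)
    r <- zv - ahat * z1
    mse <- sum(r * r) / (n - 1)
    c(mse0 = mse0, mse = mse)
  }
  obs <- k_parts(x)
  expected <- (sum(diag(C)) - n / sum(solve(C))) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected
  p <- NA_real_
  if (n_rand > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_rand)) {
      mp <- k_parts(sample(x))
      if (mp["mse"] <= obs["mse"]) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_rand + 1)
  }
  structure(list(statistic = "BlombergK", estimate = unname(K),
                 p_value = p, n_rand = n_rand),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(x$statistic, "=", format(x$estimate, digits = 4))
  if (!is.na(x$p_value)) cat(", p =", format(x$p_value, digits = 4))
  cat("\n")
  invisible(x)
}

lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the branch-length transform lambda in
#' `[0, 1]` that multiplies the off-diagonal (shared-path) entries of the
#' Brownian-motion covariance; lambda = 1 is Brownian motion, lambda = 0
#' removes all phylogenetic covariance. The p-value is a likelihood-ratio
#' test of lambda = 0 on one degree of freedom (optionally halved to respect
#' the boundary).
#'
#' @inheritParams blomberg_k
#' @param halve_boundary If `TRUE`, halve the chi-square tail probability to
#'   account for the lambda = 0 boundary.
#' @return A `"signal_result"` with `estimate`, `loglik`, `loglik_null`
#'   (lambda = 0) and `p_value`.
#' @export
pagel_lambda_continuous <- function(tree, x, halve_boundary = FALSE) {
  x <- match_tip_values(tree, x)
  n <- length(x)
  if (n < 4) stop("lambda estimation needs at least 4 tips", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  ll_at <- function(lam) {
    Ch <- tryCatch(chol(lambda_cov(C, lam)), error = function(e)
      stop("singular phylogenetic covariance; check for duplicate ",
           "zero-length tips", call. = FALSE))
    bm_profile(Ch, x)$loglik
  }
  opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-8)
  # the optimum can sit at a boundary the interior search never visits
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_at(0), ll_at(1))
  best <- which.max(lls)
  lam <- cand[best]
  ll <- lls[best]
  ll0 <- lls[2]
  lrt <- 2 * (ll - ll0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (halve_boundary) p <- p / 2
  structure(list(statistic = "PagelLambdaContinuous", estimate = lam,
                 loglik = ll, loglik_null = ll0, p_value = p,
                 n_rand = NA_integer_),
            class = "signal_result")
}

#' Lambda branch-length transform of an ultrametric tree
#'
#' Internal branches are multiplied by `lambda` and terminal branches
#' extended so every tip keeps its original depth.
#'
#' @param tree Ultrametric `"phylo"` tree.
#' @param lambda Value in `[0, 1]`.
#' @return The transformed `"phylo"` tree.
#' @export
lambda_transform_tree <- function(tree, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  chk <- stopifnot_ultrametric(tree, what = "the lambda transform")
  d <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  depth <- chk$depth
  tr <- tree
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2L]
    if (ch <= n_tip) {
      p <- tr$edge[k, 1L]
      tr$edge.length[k] <- depth - lambda * d[p]
    } else {
      tr$edge.length[k] <- lambda * tr$edge.length[k]
    }
  }
  tr
}

#' Pagel's lambda for a discrete trait
#'
#' Joint maximum likelihood of the lambda tree transform and the Mk rates:
#' for each candidate lambda the tree is rescaled (internal branches times
#' lambda, tip depths preserved) and the Mk model refitted; the reported
#' p-value is the likelihood-ratio test against lambda = 0 (the star tree
#' with the same tip depths).
#'
#' @inheritParams mk_loglik
#' @param n_starts Starts for the inner Mk fits.
#' @param seed Integer seed for the inner fits.
#' @param halve_boundary Halve the chi-square tail for the boundary null.
#' @return A `"signal_result"` with `estimate`, `loglik`, `loglik_null` and
#'   `p_value`.
#' @export
pagel_lambda_discrete <- function(tree, tip_states, spec, n_starts = 3,
                                  seed = 1, halve_boundary = FALSE) {
  stopifnot_ultrametric(tree, what = "discrete lambda")
  ll_at <- function(lam) {
    fit_mk(lambda_transform_tree(tree, lam), tip_states, spec,
           n_starts = n_starts, seed = seed)$loglik
  }
  opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-4)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_at(0), ll_at(1))
  best <- which.max(lls)
  lrt <- 2 * (lls[best] - lls[2])
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (halve_boundary) p <- p / 2
  structure(list(statistic = "PagelLambdaDiscrete", estimate = cand[best],
                 loglik = lls[best], loglik_null = lls[2], p_value = p,
                 n_rand = NA_integer_),
            class = "signal_result")
}

#' Phylogenetic ANOVA
#'
#' Classical one-way F statistic on the tip data, with significance assessed
#' against a null distribution of F values obtained by simulating the
#' response as Brownian motion on the tree (rate set to its phylogenetic
#' maximum-likelihood estimate from the observed data), so the test accounts
#' for the non-independence of related species.
#'
#' @param tree A `"phylo"` tree.
#' @param groups Named factor (or character) of group membership per tip.
#' @param y Named numeric response per tip.
#' @param n_sim Number of Brownian-motion null simulations.
#' @param seed Integer seed.
#' @return A list of class `"phyl_anova"` with `F`, `p_value`, `group_means`
#'   and `n_sim`.
#' @export
phyl_anova <- function(tree, groups, y, n_sim = 1000, seed = NULL) {
  y <- match_tip_values(tree, y, "response")
  groups <- factor(match_tip_values(tree, groups, "groups"))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members",
                                   call. = FALSE)
  f_stat <- function(v) {
    gm <- tapply(v, groups, mean)
    ng <- tabulate(groups)
    grand <- mean(v)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum((v - gm[groups])^2)
    dfb <- nlevels(groups) - 1
    dfw <- length(v) - nlevels(groups)
    (ssb / dfb) / (ssw / dfw)
  }
  Fobs <- f_stat(y)
  C <- ape::vcv.phylo(tree)
  Ch <- chol(C)
  prof <- bm_profile(Ch, y)
  if (!is.null(seed)) set.seed(seed)
  L <- t(Ch) * sqrt(prof$sig2)
  Fnull <- vapply(seq_len(n_sim), function(i) {
    f_stat(prof$ahat + as.vector(L %*% stats::rnorm(length(y))))
  }, numeric(1))
  p <- (sum(Fnull >= Fobs) + 1) / (n_sim + 1)
  structure(list(F = Fobs, p_value = p,
                 group_means = tapply(y, groups, mean), n_sim = n_sim),
            class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat("phylogenetic ANOVA: F =", format(x$F, digits = 4),
      "p =", format(x$p_value, digits = 4),
      paste0("(", x$n_sim, " BM simulations)\n"))
  invisible(x)
}
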