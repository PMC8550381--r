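#' Assemble a pipeline run configuration
#'
#' Either `tree` + `traits` (user data) or `scenario` (synthetic data) must
#' be given. All stage randomness derives from the single `seed`.
#'
#' @param tree A `"phylo"` tree or path to a Newick/NEXUS file.
#' @param traits A trait table (see [read_trait_table()]) or CSV path.
#' @param scenario A [sim_scenario()] generating tree and discrete states.
#' @param seed Master integer seed.
#' @param analyses Character subset of `c("coding","asr","signal","ltt","sse")`.
#' @param settings Named list of stage settings; see Details.
#' @details Settings (with defaults): `gap_k = 3` classes for size coding;
#'   `mk_starts = 5`, `simmap_M = 100`; `signal_n_rand = 1000`,
#'   `anova_n_sim = 1000`; `mccr_n_total = NULL` (skip MCCR), `mccr_reps =
#'   1000`; `sse_trait = "size"`, `sse_starts = 10`, `sse_rho = NULL`
#'   (model-set defaults), `recon_min_weight = 0.01`, `bm_sig2 = 1`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tree = NULL, traits = NULL, scenario = NULL,
                       seed = 1,
                       analyses = c("coding", "asr", "signal", "ltt", "sse"),
                       settings = list()) {
  if (is.null(scenario) && is.null(tree)) {
    stop("give either a tree (+ traits) or a scenario", call. = FALSE)
  }
  defaults <- list(gap_k = 3, mk_starts = 5, simmap_M = 100,
                   signal_n_rand = 1000, anova_n_sim = 1000,
                   mccr_n_total = NULL, mccr_reps = 1000,
                   sse_trait = "size", sse_starts = 10, sse_rho = NULL,
                   recon_min_weight = 0.01, bm_sig2 = 1)
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown)) stop("unknown settings: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(settings)] <- settings
  structure(list(tree = tree, traits = traits, scenario = scenario,
                 seed = seed, analyses = analyses, settings = defaults),
            class = "run_config")
}

#' Run the full trait-diversification pipeline
#'
#' Executes the enabled stages in their logical order — trait coding,
#' ancestral states and stochastic mapping, phylogenetic signal,
#' lineage-through-time diagnostics, and the SSE model set with ranking,
#' model averaging and marginal reconstruction — and returns all stage
#' results in one bundle. A stage failure aborts with a stage-labelled
#' error; completed stage results are attached to the error condition.
#'
#' @param config A [run_config()].
#' @return A list of class `"pipeline_result"` keyed by stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  s <- config$settings
  seed <- config$seed
  res <- list(config = config, log = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$partial <- res
      stop(cond)
    })
    res$log[[name]] <<- list(seconds = as.numeric(Sys.time() - t0,
                                                  units = "secs"))
    out
  }

  # --- data acquisition -----------------------------------------------
  res$data <- stage("data", {
    if (!is.null(config$scenario)) {
      sim <- simulate_sse_tree(config$scenario, seed = seed)
      cont <- simulate_continuous_traits(sim$tree, sig2 = s$bm_sig2,
                                         lambda = 1, seed = seed + 1)
      size_states <- decode_binary_pair(sim$tip_states)
      list(tree = sim$tree, codes = sim$tip_states,
           size_states = size_states, continuous = cont,
           ecotype = NULL, sim = sim)
    } else {
      tree <- if (inherits(config$tree, "phylo")) config$tree
              else read_tree(config$tree)
      traits <- read_trait_table(config$traits, tree)
      gc <- gap_code(traits$total_length_cm, k = s$gap_k)
      size_states <- stats::setNames(as.character(gc$assignment),
                                     traits$species)
      eco <- stats::setNames(traits$ecotype, traits$species)
      list(tree = tree, gap = gc,
           codes = encode_binary_pair(size_states),
           size_states = size_states,
           continuous = stats::setNames(traits$total_length_cm,
                                        traits$species),
           body_depth = stats::setNames(traits$body_depth_pct,
                                        traits$species),
           ecotype = eco)
    }
  })
  tree <- res$data$tree
  size_states <- res$data$size_states

  if ("asr" %in% config$analyses) {
    res$asr <- stage("asr", {
      alph <- sort(unique(size_states))
      specs <- list(
        ER = build_rate_matrix(alph, "ER"),
        SYM = build_rate_matrix(alph, "SYM"),
        ARD = build_rate_matrix(alph, "ARD"))
      if (length(alph) == 3 && all(alph %in% c("S", "M", "L"))) {
        specs$ARD_constrained <- build_rate_matrix(c("S", "M", "L"), "ARD",
                                                   constrained = TRUE)
      }
      fits <- lapply(specs, function(sp)
        fit_mk(tree, size_states, sp, n_starts = s$mk_starts, seed = seed))
      tab <- data.frame(
        model = names(fits),
        free_parameters = vapply(fits, `[[`, numeric(1), "k"),
        lnL = vapply(fits, `[[`, numeric(1), "loglik"),
        AIC = vapply(fits, `[[`, numeric(1), "AIC"))
      tab$delta_AIC <- tab$AIC - min(tab$AIC)
      map_spec <- specs[[if ("ARD_constrained" %in% names(specs))
        "ARD_constrained" else "ARD"]]
      map_fit <- fits[[if ("ARD_constrained" %in% names(specs))
        "ARD_constrained" else "ARD"]]
      marg <- marginal_asr(tree, size_states, map_spec, map_fit$rates)
      maps <- sample_stochastic_maps(tree, size_states, map_spec,
                                     map_fit$rates, M = s$simmap_M,
                                     seed = seed + 2)
      list(fit_table = tab, fits = fits, marginals = marg, maps = maps,
           counts = count_transitions(maps), map_spec = map_spec)
    })
  }

  if ("signal" %in% config$analyses) {
    res$signal <- stage("signal", {
      out <- list()
      x <- res$data$continuous
      out$K_length <- blomberg_k(tree, x, n_rand = s$signal_n_rand,
                                 seed = seed + 3)
      out$lambda_length <- pagel_lambda_continuous(tree, x)
      if (!is.null(res$data$body_depth)) {
        out$K_depth <- blomberg_k(tree, res$data$body_depth,
                                  n_rand = s$signal_n_rand, seed = seed + 4)
        out$lambda_depth <- pagel_lambda_continuous(tree, res$data$body_depth)
      }
      alph <- sort(unique(size_states))
      out$lambda_discrete_size <- pagel_lambda_discrete(
        tree, size_states, build_rate_matrix(alph, "ER"), seed = seed + 5)
      if (!is.null(res$data$ecotype)) {
        out$anova_size_by_ecotype <- phyl_anova(
          tree, res$data$ecotype, x, n_sim = s$anova_n_sim, seed = seed + 6)
      }
      out
    })
  }

  if ("ltt" %in% config$analyses) {
    res$ltt <- stage("ltt", {
      curve <- ltt_curve(tree)
      gam <- gamma_statistic(tree)
      mccr <- NULL
      if (!is.null(s$mccr_n_total)) {
        mccr <- mccr_test(tree, n_total = s$mccr_n_total,
                          n_reps = s$mccr_reps, seed = seed + 7)
      }
      plain <- mccr_test(tree, n_total = length(tree$tip.label),
                         n_reps = s$mccr_reps, seed = seed + 8)
      list(curve = curve, gamma = gam, mccr = mccr, plain_test = plain)
    })
  }

  if ("sse" %in% config$analyses) {
    res$sse <- stage("sse", {
      codes <- res$data$codes
      set <- build_model_set(s$sse_trait, rho = s$sse_rho)
      fits <- vector("list", length(set))
      names(fits) <- names(set)
      for (i in seq_along(set)) {
        fits[[i]] <- fit_sse(tree, codes, set[[i]],
                             n_starts = s$sse_starts, seed = seed + 10 + i)
      }
      ranking <- rank_models(fits)
      w <- ranking$weight[match(names(fits), ranking$model)]
      recons <- vector("list", length(fits))
      for (i in seq_along(fits)) {
        if (w[i] > s$recon_min_weight) {
          recons[[i]] <- marginal_reconstruction_sse(
            tree, codes, set[[i]], fits[[i]]$par)
        }
      }
      avg <- model_average_rates(fits, recons,
                                 min_weight = s$recon_min_weight)
      list(fits = fits, ranking = ranking, reconstructions = recons,
           averaged_rates = avg)
    })
  }
  structure(res, class = "pipeline_result")
}

#' Write a pipeline report bundle
#'
#' Emits the stage results as CSV/JSON files: the trait coding table, the
#' Mk fit table, transition-count table (with structural zeros flagged),
#' the signal table, gamma results, the SSE ranking in the
#' `model,description,free_parameters,lnL,AIC,AICc,delta_AIC,weight`
#' schema, model-averaged rates, and a `summary.json` keyed by stage.
#'
#' @param results A `"pipeline_result"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(inherits(results, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, fname) {
    path <- file.path(out_dir, fname)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  summary <- list(seed = results$config$seed)

  if (!is.null(results$data$gap)) {
    gc <- results$data$gap
    put(data.frame(species = names(results$data$size_states),
                   state = unname(results$data$size_states)),
        "size_coding.csv")
    summary$coding <- list(k = gc$k, breakpoints = gc$breakpoints)
  }
  if (!is.null(results$asr)) {
    put(results$asr$fit_table, "mk_fits.csv")
    ct <- results$asr$counts
    states <- rownames(ct$mean)
    mask <- results$asr$map_spec$index == 0 & !diag(length(states))
    long <- expand.grid(from = states, to = states, stringsAsFactors = FALSE)
    long <- long[long$from != long$to, ]
    long$mean <- ct$mean[cbind(long$from, long$to)]
    long$modal <- ct$modal[cbind(long$from, long$to)]
    long$structural_zero <- mask[cbind(long$from, long$to)]
    put(long, "transition_counts.csv")
    summary$asr <- list(best_model = results$asr$fit_table$model[
      which.min(results$asr$fit_table$AIC)])
  }
  if (!is.null(results$signal)) {
    rows <- lapply(names(results$signal), function(nm) {
      o <- results$signal[[nm]]
      if (inherits(o, "signal_result")) {
        data.frame(trait = nm, statistic = o$statistic,
                   estimate = o$estimate, p_value = o$p_value,
                   n_rand = if (is.na(o$n_rand)) NA_integer_ else o$n_rand)
      } else if (inherits(o, "phyl_anova")) {
        data.frame(trait = nm, statistic = "phylANOVA_F", estimate = o$F,
                   p_value = o$p_value, n_rand = o$n_sim)
      }
    })
    put(do.call(rbind, rows), "signal.csv")
    summary$signal <- lapply(results$signal, function(o)
      list(estimate = if (!is.null(o$estimate)) o$estimate else o$F,
           p = o$p_value))
  }
  if (!is.null(results$ltt)) {
    put(results$ltt$curve, "ltt.csv")
    g <- results$ltt$gamma
    gp <- results$ltt$plain_test
    grow <- data.frame(test = "plain", gamma = gp$gamma, p_value = gp$p_value)
    if (!is.null(results$ltt$mccr)) {
      m <- results$ltt$mccr
      grow <- rbind(grow, data.frame(test = "mccr", gamma = m$gamma,
                                     p_value = m$p_value))
    }
    put(grow, "gamma.csv")
    summary$ltt <- list(gamma = g$gamma, n = g$n_tips)
  }
  if (!is.null(results$sse)) {
    put(results$sse$ranking, "sse_ranking.csv")
    put(results$sse$averaged_rates, "averaged_rates.csv")
    write_annotated_tree(results$data$tree,
                         results$sse$averaged_rates["net_div"],
                         results$sse$averaged_rates$node,
                         file = file.path(out_dir, "averaged_rates.nwk"))
    files <- c(files, file.path(out_dir, "averaged_rates.nwk"))
    recs <- results$sse$reconstructions
    have <- which(!vapply(recs, is.null, logical(1)))
    if (length(have)) {
      long <- do.call(rbind, lapply(have, function(i) {
        r <- recs[[i]]
        do.call(rbind, lapply(seq_along(r$nodes), function(z)
          data.frame(model = names(results$sse$fits)[i],
                     node_id = r$nodes[z],
                     state = colnames(r$composite),
                     probability = unname(r$composite[z, ]))))
      }))
      put(long, "reconstructions.csv")
    }
    summary$sse <- list(best_model = results$sse$ranking$model[1],
                        best_weight = results$sse$ranking$weight[1])
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "summary.json"))
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
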