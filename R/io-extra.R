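#' Write a Newick string annotated with per-node rates
#'
#' Attaches per-node quantities (e.g. model-averaged net diversification)
#' as bracketed comments `[&key=value]` after each node, the convention
#' annotation-aware tree viewers read.
#'
#' @param tree A `"phylo"` tree.
#' @param values Named list (or data.frame) of numeric vectors indexed by
#'   node number (tips then internal nodes, `ape` numbering); nodes absent
#'   from a vector are left unannotated.
#' @param nodes Node numbers the rows of `values` refer to.
#' @param file Optional output path.
#' @param digits Significant digits for branch lengths and annotations.
#' @return The annotated Newick string (invisibly if written to file).
#' @export
write_annotated_tree <- function(tree, values, nodes, file = NULL,
                                 digits = 8) {
  values <- as.data.frame(values)
  stopifnot(nrow(values) == length(nodes))
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ann <- function(nd) {
    r <- match(nd, nodes)
    if (is.na(r)) return("")
    paste0("[&", paste(sprintf("%s=%.*g", names(values), digits,
                               unlist(values[r, ])), collapse = ","), "]")
  }
  build <- function(nd) {
    if (nd <= n_tip) return(paste0(tree$tip.label[nd], ann(nd)))
    ke <- kids[[as.character(nd)]]
    parts <- vapply(ke, function(k) {
      paste0(build(tree$edge[k, 2L]), ":",
             format(tree$edge.length[k], digits = digits))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", ann(nd))
  }
  s <- paste0(build(n_tip + 1L), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Serialize and restore a pipeline configuration
#'
#' Round-trips a [run_config()] through JSON. Tree and trait inputs must be
#' file paths (in-memory objects cannot be serialized losslessly);
#' synthetic scenarios are stored by their generating parameters.
#'
#' @param config A `"run_config"`.
#' @param path JSON file path.
#' @return `write_run_config` the path invisibly; `read_run_config` the
#'   restored `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(config$tree, "phylo") || is.data.frame(config$traits)) {
    stop("only path-based tree/trait inputs can be serialized", call. = FALSE)
  }
  x <- list(tree = config$tree, traits = config$traits, seed = config$seed,
            analyses = config$analyses, settings = config$settings)
  if (!is.null(config$scenario)) {
    sc <- unclass(config$scenario)
    sc$q <- as.vector(sc$q)
    x$scenario <- sc
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- NULL
  if (!is.null(x$scenario)) {
    sc <- x$scenario
    scenario <- sim_scenario(sc$generator, lambda = sc$lambda, mu = sc$mu,
                             q = matrix(sc$q, sc$k, sc$k),
                             target_tips = sc$target_tips,
                             stop_time = sc$stop_time, rho = sc$rho,
                             obs_map = sc$obs_map,
                             tip_window = sc$tip_window,
                             max_attempts = sc$max_attempts)
  }
  settings <- x$settings
  # JSON null -> NULL list entries need restoring
  settings <- settings[!vapply(settings, is.null, logical(1))]
  run_config(tree = x$tree, traits = x$traits, scenario = scenario,
             seed = x$seed, analyses = x$analyses, settings = settings)
}
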