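#' Read a time-calibrated tree from Newick or NEXUS text
#'
#' Parses a rooted phylogeny with branch lengths and validates it for use in
#' downstream analyses. Polytomies are preserved. The returned object is a
#' standard `ape` `"phylo"` tree; all functions in this package consume that
#' representation.
#'
#' @param text A Newick string, or a path to a file containing Newick or
#'   NEXUS (`#NEXUS` header) formatted trees.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_tree("(A:1.0,B:1.0);")
#' node_depths(tr)
#' @export
read_tree <- function(text) {
  txt <- text
  if (length(txt) == 1 && !grepl("[(;]", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  }
  tr <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    ape::read.nexus(tf)
  } else {
    n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
    n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
    if (n_open != n_close) {
      stop("unbalanced parentheses in Newick input: ", n_open, " '(' vs ",
           n_close, " ')'", call. = FALSE)
    }
    tr <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
    if (is.null(tr)) stop("Newick parse error: no tree found in input",
                          call. = FALSE)
    tr
  }
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  validate_tree(tr)
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree A `"phylo"` tree.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly if written to file).
#' @export
write_tree <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}

#' Node depths (time from the root) and heights (time before present)
#'
#' `node_depths()` returns, for every tip and internal node, the sum of branch
#' lengths from the root. `node_heights()` returns time before the present,
#' i.e. maximum tip depth minus depth, so tips of an ultrametric tree sit at
#' height 0 and the root at the tree depth.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @return Numeric vector indexed by node number (tips `1..n`, then
#'   internal nodes).
#' @export
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  root <- n_tip + 1L
  eo <- reorder_edges_preorder(tree)
  for (k in eo) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    depth[ch] <- depth[p] + tree$edge.length[k]
  }
  depth
}

#' @rdname node_depths
#' @export
node_heights <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

# edge indices ordered so parents are visited before children
reorder_edges_preorder <- function(tree) {
  rev(reorder_edges_postorder(tree))
}

# edge indices ordered so every child edge precedes its parent edge
reorder_edges_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  tr
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' All root-to-tip path lengths must agree to within `tol` times the tree
#' depth (boundary inclusive).
#'
#' @param tree A `"phylo"` tree.
#' @param tol Relative tolerance (default `1e-6`).
#' @return A list with `ultrametric` (logical), `max_deviation` (absolute
#'   spread of tip depths) and `depth` (maximum root-to-tip depth).
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  depth <- max(d)
  dev <- depth - min(d)
  list(ultrametric = dev <= tol * depth + .Machine$double.eps,
       max_deviation = dev, depth = depth)
}

stopifnot_ultrametric <- function(tree, tol = 1e-6, what = "this analysis") {
  chk <- check_ultrametric(tree, tol)
  if (!chk$ultrametric) {
    stop(what, " requires an ultrametric (extant-only, time-calibrated) tree; ",
         "tip depth spread is ", format(chk$max_deviation),
         " against depth ", format(chk$depth), call. = FALSE)
  }
  invisible(chk)
}
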