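#' Trees with an explicit branch-length scale
#'
#' The pipeline manipulates rooted `ape::phylo` trees on two different
#' branch-length scales: raw expected substitutions per site (as estimated
#' from sequence data) and relative time (ultrametric, root age normalised
#' to 1 by the smoother). Confusing the two is the main failure mode when
#' mixing markers, so the scale is carried as explicit metadata on the tree
#' object and never inferred from the branch lengths themselves.
#'
#' @param tree an object of class `phylo`.
#' @param scale one of `"substitutions"` or `"relative_time"`.
#' @return `tree_scale()` returns the scale string; `set_tree_scale()`
#'   returns the tree with the attribute set.
#' @export
tree_scale <- function(tree) {
  attr(tree, "ecm_scale") %||% "substitutions"
}

#' @rdname tree_scale
#' @export
set_tree_scale <- function(tree, scale = c("substitutions", "relative_time")) {
  scale <- match.arg(scale)
  attr(tree, "ecm_scale") <- scale
  tree
}

#' Read a rooted Newick tree
#'
#' Reads a single rooted tree with branch lengths on all non-root edges.
#' The branch-length scale is taken from (in order of precedence) the
#' `scale` argument, a sidecar file `<path>.meta.json` written by
#' [write_newick()], or the default `"substitutions"`.
#'
#' @param path file containing one Newick tree.
#' @param scale optional explicit scale (see [tree_scale()]).
#' @param allow_polytomy if `FALSE` (default) a multifurcation at the root
#'   (ape's representation of an unrooted tree) is an error.
#' @return a `phylo` tree with a scale attribute.
#' @export
read_newick <- function(path, scale = NULL, allow_polytomy = FALSE) {
  if (!file.exists(path)) stop_ecm("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(gsub("[;[:space:]]", "", txt)))
    stop_ecm("empty tree in ", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_ecm("malformed Newick in ", path)
  if (inherits(tree, "multiPhylo") || is.list(tree$tip.label[[1]]))
    stop_ecm("expected a single tree in ", path)
  root <- ape::Ntip(tree) + 1L
  if (!allow_polytomy && sum(tree$edge[, 1] == root) > 2L)
    stop_ecm("tree in ", path, " is multifurcating at the root ",
             "(unrooted?); pass allow_polytomy = TRUE to accept")
  if (is.null(tree$edge.length))
    stop_ecm("tree in ", path, " has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    lab <- if (bad <= ape::Ntip(tree)) tree$tip.label[bad] else
      paste0("internal node ", bad)
    stop_ecm("missing branch length above ", lab, " in ", path)
  }
  if (is.null(scale)) {
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar))
      scale <- jsonlite::read_json(sidecar)$scale
  }
  set_tree_scale(tree, scale %||% "substitutions")
}

#' Write a Newick tree (with optional scale sidecar)
#'
#' @param tree a `phylo` tree.
#' @param path output file.
#' @param sidecar write `<path>.meta.json` recording the branch-length
#'   scale so that [read_newick()] can recover it.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, sidecar = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  if (sidecar)
    jsonlite::write_json(list(scale = tree_scale(tree)),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

node_depths <- function(tree) {
  # root-to-node path lengths, for all nodes (root depth 0)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  }
  depth
}

#' Deviation from ultrametricity
#'
#' Returns the maximum over tips of the absolute difference between the
#' root-to-tip path length and the mean root-to-tip path length. A tree
#' passes at tolerance `tol` iff the returned value is `<= tol`.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param tol tolerance used for the `pass` attribute.
#' @return the maximum deviation, with attribute `pass`.
#' @export
check_ultrametric <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(abs(d - mean(d)))
  structure(dev, pass = dev <= tol)
}

#' All-pairs patristic distances
#'
#' Sum of branch lengths on the path between every pair of tips.
#'
#' @param tree a `phylo` tree with nonnegative branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_ecm("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_ecm("negative branch length in tree")
  ape::cophenetic.phylo(tree)
}

#' Node ages of an ultrametric tree
#'
#' @param tree ultrametric `phylo` tree.
#' @return numeric vector of ages (time before present) for all nodes,
#'   tips first.
#' @keywords internal
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}
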