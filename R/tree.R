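# Time-calibrated tree handling. Trees are ape "phylo" objects; the package
# imposes the extra contract checked by validate_tree(): rooted, strictly
# binary, ultrametric within a relative tolerance, non-negative branch
# lengths, unique tip labels. Time runs from 0 at the root to T at the
# present, so rate functions of the form sigma0^2 * exp(r * t) decline (for
# r < 0) since the root.

#' Parse a Newick string into a validated time tree
#'
#' Reads a rooted, binary, ultrametric chronogram. Branch lengths are
#' interpreted as time (Myr). Polytomies and non-ultrametric trees are
#' rejected; the ultrametricity check names the offending tip.
#'
#' @param text Newick string (with branch lengths).
#' @param tol_rel Relative ultrametricity tolerance; tip depths may differ
#'   from the root age by at most `tol_rel * T`. Chronograms assembled from
#'   posterior samples carry rounding noise, hence the default `1e-6`.
#' @return An object of class `phylo` passing [validate_tree()].
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)  # 2
parse_newick <- function(text, tol_rel = 1e-6) {
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop_("could not parse Newick string")
  validate_tree(tree, tol_rel = tol_rel)
  tree
}

#' Validate the package's tree contract
#'
#' @param tree A `phylo` object.
#' @param tol_rel Relative ultrametricity tolerance (see [parse_newick()]).
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree, tol_rel = 1e-6) {
  if (!inherits(tree, "phylo")) stop_("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop_("tree has no branch lengths")
  if (!ape::is.rooted(tree)) stop_("tree must be rooted")
  if (!ape::is.binary(tree)) stop_("tree contains polytomies; only binary trees are supported")
  if (any(tree$edge.length < 0)) stop_("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop_("duplicate tip labels")
  d <- node_depths(tree)
  ntip <- length(tree$tip.label)
  td <- d[seq_len(ntip)]
  T <- stats::median(td)
  off <- abs(td - T)
  if (any(off > tol_rel * max(T, .Machine$double.eps))) {
    worst <- which.max(off)
    stop_(sprintf("tree is not ultrametric: tip '%s' has depth %.8g, root age %.8g",
                  tree$tip.label[worst], td[worst], T))
  }
  invisible(tree)
}

#' Node depths (time since the root)
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over node ids (tips `1..n`, then internal nodes);
#'   the root has depth 0.
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Root age of an ultrametric tree
#' @param tree A `phylo` object.
#' @return Root-to-tip time T.
#' @export
tree_height <- function(tree) {
  d <- node_depths(tree)
  stats::median(d[seq_along(tree$tip.label)])
}

# Parent lookup: parent[v] = parent node of v (0 for the root).
parent_vector <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  p <- integer(nn)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# Edge index ending at each node (0 for the root).
edge_to_node <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  e <- integer(nn)
  e[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  e
}

# Row mapping between two orderings of the same edge matrix (node ids are
# preserved by ape::reorder.phylo, only the row order changes).
edge_order_map <- function(a, b) {
  match(paste(a$edge[, 1], a$edge[, 2]), paste(b$edge[, 1], b$edge[, 2]))
}

# Ordered edge indices on the path root -> node (possibly empty).
root_path_edges <- function(tree, node) {
  p <- parent_vector(tree)
  e <- edge_to_node(tree)
  root <- length(tree$tip.label) + 1L
  path <- integer(0)
  v <- node
  while (v != root) {
    path <- c(e[v], path)
    v <- p[v]
  }
  path
}

#' Segments of the shared root-to-MRCA path of two tips
#'
#' Closed-form covariances for regime-dependent models integrate the rate
#' along the path shared by two tips, i.e. from the root down to their most
#' recent common ancestor. For `i == j` the full root-to-tip path is
#' returned.
#'
#' @param tree A validated `phylo`.
#' @param regimes Optional [regime_history()]; when `NULL` each branch is a
#'   single unlabeled segment.
#' @param i,j Tip labels or indices.
#' @return A data frame with columns `t0`, `t1` (absolute times), `duration`
#'   and `regime`, ordered root-ward first. Zero rows when the MRCA is the
#'   root.
#' @export
shared_path_segments <- function(tree, regimes = NULL, i, j) {
  tip_id <- function(x) {
    if (is.character(x)) {
      id <- match(x, tree$tip.label)
      if (is.na(id)) stop_(sprintf("unknown tip '%s'", x))
      id
    } else {
      x <- as.integer(x)
      if (x < 1L || x > length(tree$tip.label)) stop_("unknown tip index")
      x
    }
  }
  i <- tip_id(i); j <- tip_id(j)
  target <- if (i == j) i else ape::getMRCA(tree, c(i, j))
  root <- length(tree$tip.label) + 1L
  out <- list()
  if (target != root) {
    d <- node_depths(tree)
    for (e in root_path_edges(tree, target)) {
      t0 <- d[tree$edge[e, 1]]
      if (is.null(regimes)) {
        segs <- stats::setNames(tree$edge.length[e], NA_character_)
      } else {
        segs <- regimes$maps[[e]]
      }
      ends <- t0 + cumsum(unname(segs))
      starts <- c(t0, ends[-length(ends)])
      out[[length(out) + 1L]] <- data.frame(
        t0 = starts, t1 = ends, duration = unname(segs),
        regime = names(segs), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(t0 = numeric(0), t1 = numeric(0),
                      duration = numeric(0), regime = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
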