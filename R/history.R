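# Piecewise-constant branch histories: regime histories ("which regime is
# lineage j in at time t") and biogeographic occupancy histories (which of K
# named areas lineage j occupies). Both are stored as one named numeric
# vector per edge of the tree, in the same orientation as the SIMMAP text
# dialect: the root-ward segment comes first, names are the states,
# values are durations summing to the branch length.

#' Construct a regime history
#'
#' @param tree Validated `phylo`.
#' @param maps List with one named numeric vector per edge (in
#'   `tree$edge` row order): segment durations named by regime label,
#'   root-ward segment first.
#' @param alphabet Allowed regime labels.
#' @return Object of class `regime_history` with fields `tree`, `maps`,
#'   `alphabet` and `root_state` (state of the root stem, taken from the
#'   first segment of the root's child edges).
#' @export
regime_history <- function(tree, maps, alphabet = c("A", "B")) {
  validate_maps(tree, maps, alphabet)
  structure(list(tree = tree, maps = maps, alphabet = alphabet,
                 root_state = root_state_of(tree, maps)),
            class = "regime_history")
}

#' Construct a biogeographic occupancy history
#'
#' States are occupancy bit patterns over `K` named areas, written as
#' strings of 0/1 of length `K` (e.g. `"10"` = present only in the first of
#' two areas). Every lineage must occupy at least one area at all times.
#'
#' @param tree Validated `phylo`.
#' @param maps Per-edge named duration vectors as in [regime_history()],
#'   with bit-pattern state names.
#' @param areas Character vector of area names (length `K >= 1`).
#' @return Object of class `biogeo_history`.
#' @export
biogeo_history <- function(tree, maps, areas) {
  if (length(areas) < 1L) stop_("need at least one area")
  K <- length(areas)
  pats <- unique(unlist(lapply(maps, names)))
  bad <- pats[nchar(pats) != K | grepl("[^01]", pats)]
  if (length(bad)) stop_(sprintf("invalid occupancy pattern(s): %s", paste(bad, collapse = ", ")))
  if (any(!grepl("1", pats))) stop_("a lineage must occupy at least one area at all times")
  validate_maps(tree, maps, alphabet = NULL)
  structure(list(tree = tree, maps = maps, areas = areas, K = K,
                 root_state = root_state_of(tree, maps)),
            class = "biogeo_history")
}

root_state_of <- function(tree, maps) {
  root <- length(tree$tip.label) + 1L
  kids <- which(tree$edge[, 1] == root)
  states <- vapply(kids, function(e) names(maps[[e]])[1], character(1))
  if (length(unique(states)) > 1L) {
    warning("root children start in different states; using the first",
            call. = FALSE)
  }
  states[1]
}

validate_maps <- function(tree, maps, alphabet = NULL) {
  ne <- nrow(tree$edge)
  if (length(maps) != ne) stop_("history must have one segment vector per edge")
  tol <- 1e-6 * max(tree_height(tree), 1)
  for (e in seq_len(ne)) {
    segs <- maps[[e]]
    if (is.null(names(segs)) || any(!nzchar(names(segs)))) {
      stop_(sprintf("edge %d: segments must be named by state", e))
    }
    if (any(segs < 0)) stop_(sprintf("edge %d: negative segment duration", e))
    if (abs(sum(segs) - tree$edge.length[e]) > tol) {
      stop_(sprintf(
        "edge %d (to node %d): segment durations sum to %.8g but branch length is %.8g",
        e, tree$edge[e, 2], sum(segs), tree$edge.length[e]))
    }
    if (!is.null(alphabet) && !all(names(segs) %in% alphabet)) {
      stop_(sprintf("edge %d: unknown state '%s'", e,
                    setdiff(names(segs), alphabet)[1]))
    }
  }
  invisible(TRUE)
}

# State on edge e at local time t (from the root-ward end of the branch).
state_at <- function(segs, tloc) {
  ends <- cumsum(unname(segs))
  names(segs)[min(which(tloc <= ends + 1e-12), length(segs))]
}

#' Parse a SIMMAP-annotated Newick string
#'
#' Reads the classic curly-brace dialect in which every branch carries an
#' annotation `{state,duration:state,duration:...}` with the root-ward
#' segment written first; the branch length is the sum of the durations.
#'
#' @param text SIMMAP Newick string.
#' @param alphabet Optional allowed state set; unknown states are rejected.
#' @param ref_tree Optional reference `phylo`: branch lengths implied by the
#'   segment durations must match it within `1e-6` (relative to tree
#'   height), otherwise the offending branch is named.
#' @return A list with fields `tree` (a `phylo`) and `maps` (per-edge named
#'   duration vectors). Use [regime_history()] / [biogeo_history()] to
#'   attach the type contract.
#' @export
#' @examples
#' h <- parse_simmap("((A:{0,0.4:1,0.6},B:{0,1}):{0,1},C:{0,2});")
#' h$maps[[which(h$tree$edge[, 2] == 1)]]  # segments of tip A's branch
parse_simmap <- function(text, alphabet = NULL, ref_tree = NULL) {
  txt <- gsub("[[:space:]]", "", paste(text, collapse = ""))
  ann <- regmatches(txt, gregexpr("\\{[^}]*\\}", txt))[[1]]
  if (!length(ann)) stop_("no SIMMAP annotations found")
  out <- txt
  for (i in seq_along(ann)) {
    out <- sub(paste0(":", ann[i]), paste0(":", i), out, fixed = TRUE)
  }
  if (grepl("\\{", out)) stop_("malformed SIMMAP annotation placement")
  tree <- ape::read.tree(text = out)
  if (is.null(tree)) stop_("could not parse SIMMAP Newick")
  idx <- as.integer(round(tree$edge.length))
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > length(ann))) {
    stop_("could not associate SIMMAP annotations with branches")
  }
  parse_one <- function(a) {
    body <- substr(a, 2, nchar(a) - 1)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ",", fixed = TRUE)
    states <- vapply(kv, `[`, character(1), 1)
    durs <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2)))
    if (any(is.na(durs))) stop_("malformed SIMMAP segment (expected state,duration)")
    stats::setNames(durs, states)
  }
  maps <- lapply(ann[idx], parse_one)
  tree$edge.length <- vapply(maps, sum, numeric(1))
  if (!is.null(alphabet)) {
    states <- unique(unlist(lapply(maps, names)))
    if (!all(states %in% alphabet)) {
      stop_(sprintf("unknown state label(s): %s",
                    paste(setdiff(states, alphabet), collapse = ", ")))
    }
  }
  if (!is.null(ref_tree)) {
    if (length(ref_tree$tip.label) != length(tree$tip.label) ||
        !all(sort(ref_tree$tip.label) == sort(tree$tip.label))) {
      stop_("SIMMAP tree does not match the reference tree's tips")
    }
    o <- match_edges(tree, ref_tree)
    tol <- 1e-6 * max(tree_height(ref_tree), 1)
    for (e in seq_along(maps)) {
      want <- ref_tree$edge.length[o[e]]
      if (abs(tree$edge.length[e] - want) > tol) {
        stop_(sprintf(
          "branch to node %d: SIMMAP segments sum to %.8g but reference branch length is %.8g",
          tree$edge[e, 2], tree$edge.length[e], want))
      }
    }
  }
  list(tree = tree, maps = maps)
}

# Map edges of tree a onto edges of tree b (same topology) by tip-set.
match_edges <- function(a, b) {
  clade_key <- function(tr) {
    ntip <- length(tr$tip.label)
    sets <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) sets[[i]] <- tr$tip.label[i]
    po <- ape::reorder.phylo(tr, "postorder")
    for (k in seq_len(nrow(po$edge))) {
      u <- po$edge[k, 1]; v <- po$edge[k, 2]
      sets[[u]] <- c(sets[[u]], sets[[v]])
    }
    vapply(tr$edge[, 2], function(v) paste(sort(sets[[v]]), collapse = "|"),
           character(1))
  }
  ka <- clade_key(a); kb <- clade_key(b)
  o <- match(ka, kb)
  if (any(is.na(o))) stop_("trees differ in topology")
  o
}

#' Serialize a history to SIMMAP Newick
#'
#' Inverse of [parse_simmap()]; segments are written root-ward first.
#'
#' @param history A [regime_history()] or [biogeo_history()] (or a list with
#'   `tree` and `maps`).
#' @return A single SIMMAP Newick string.
#' @export
write_simmap <- function(history) {
  tree <- history$tree; maps <- history$maps
  e2n <- edge_to_node(tree)
  ntip <- length(tree$tip.label)
  branch_txt <- function(e) {
    segs <- maps[[e]]
    paste0("{", paste(paste(names(segs), vapply(unname(segs), fmt_num, character(1)),
                            sep = ","), collapse = ":"), "}")
  }
  desc <- function(v) {
    if (v <= ntip) {
      base <- tree$tip.label[v]
    } else {
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      base <- paste0("(", paste(vapply(kids, desc, character(1)), collapse = ","), ")")
    }
    if (e2n[v] > 0L) paste0(base, ":", branch_txt(e2n[v])) else base
  }
  paste0(desc(ntip + 1L), ";")
}

#' Collapse a 3-state history onto the 2-state tropical/temperate contrast
#'
#' Species breeding in both zones are grouped with temperate breeders, so
#' the "tropical" regime means exclusively tropical; adjacent same-label
#' segments are merged. Collapsing is a projection: applying it twice equals
#' applying it once.
#'
#' @param history A [regime_history()] whose alphabet contains the states to
#'   collapse.
#' @param from State to remove (default `"both"`).
#' @param to State absorbing it (default `"temperate"`).
#' @return A `regime_history` on the reduced alphabet.
#' @export
collapse_regimes <- function(history, from = "both", to = "temperate") {
  maps <- lapply(history$maps, function(segs) {
    nm <- names(segs)
    nm[nm == from] <- to
    merge_adjacent(stats::setNames(unname(segs), nm))
  })
  alphabet <- setdiff(history$alphabet, from)
  if (!to %in% alphabet) alphabet <- c(alphabet, to)
  regime_history(history$tree, maps, alphabet = alphabet)
}

merge_adjacent <- function(segs) {
  if (length(segs) < 2L) return(segs)
  keep <- c(TRUE, names(segs)[-1] != names(segs)[-length(segs)])
  grp <- cumsum(keep)
  out <- tapply(unname(segs), grp, sum)
  stats::setNames(as.numeric(out), names(segs)[keep])
}

#' Collapse a single breeding-zone state label
#'
#' @param state One of `"tropical"`, `"temperate"`, `"both"`.
#' @return `"tropical"` or `"temperate"` (the `"both"` category is grouped
#'   with `"temperate"`).
#' @export
collapse_state <- function(state) {
  if (!all(state %in% c("tropical", "temperate", "both"))) {
    stop_("unknown state; expected tropical/temperate/both")
  }
  ifelse(state == "tropical", "tropical", "temperate")
}

#' Regime labels of the tips
#'
#' @param history A `regime_history` or `biogeo_history`.
#' @return Character vector of the state at the tip end of each terminal
#'   branch, named by tip label.
#' @export
tip_states <- function(history) {
  tree <- history$tree
  ntip <- length(tree$tip.label)
  e2n <- edge_to_node(tree)
  st <- vapply(seq_len(ntip), function(i) {
    segs <- history$maps[[e2n[i]]]
    names(segs)[length(segs)]
  }, character(1))
  stats::setNames(st, tree$tip.label)
}
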