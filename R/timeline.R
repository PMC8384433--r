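# Event timeline: the piecewise-constant backbone shared by the moment
# propagation and the trait simulators. Between consecutive events
# (branchings, regime switches, occupancy changes) the set of alive
# lineages, their regimes and the sympatry matrix A(t) are all constant.
# Lineages are identified by the child node of the edge they sit on.

#' Build the event timeline of a tree with optional histories
#'
#' @param tree Validated `phylo`.
#' @param regimes Optional [regime_history()] on the same tree.
#' @param biogeo Optional [biogeo_history()] on the same tree; when absent
#'   the sympatry matrix is all ones (full sympatry), so biogeography-aware
#'   models reduce exactly to their sympatric counterparts.
#' @return Object of class `event_timeline`: a list with `times` (strictly
#'   increasing event times from 0 to T) and `intervals`, one entry per
#'   inter-event interval carrying `t0`, `t1`, `lineages` (child-node ids of
#'   the alive edges), `parent` (for each lineage, the lineage id it
#'   descends from at the interval start; `NA` when it continues), `regime`,
#'   `A` (symmetric 0/1 sympatry matrix with unit diagonal) and `d` (row
#'   sums of `A` over same-regime lineages, self included).
#' @export
build_event_timeline <- function(tree, regimes = NULL, biogeo = NULL) {
  for (h in list(regimes, biogeo)) {
    if (!is.null(h) && !isTRUE(all.equal(h$tree$edge, tree$edge))) {
      stop_("history is defined on a different topology than the tree")
    }
  }
  d <- node_depths(tree)
  ntip <- length(tree$tip.label)
  T <- tree_height(tree)
  tol <- 1e-9 * max(T, 1)

  ev <- c(0, d[(ntip + 2L):(ntip + tree$Nnode)], T)
  seg_times <- function(history) {
    if (is.null(history)) return(numeric(0))
    unlist(lapply(seq_along(history$maps), function(e) {
      segs <- history$maps[[e]]
      if (length(segs) < 2L) return(numeric(0))
      d[tree$edge[e, 1]] + cumsum(unname(segs))[-length(segs)]
    }))
  }
  ev <- c(ev, seg_times(regimes), seg_times(biogeo))
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > tol)]  # merge simultaneous events
  if (abs(ev[length(ev)] - T) > tol) ev <- c(ev, T)

  p <- parent_vector(tree)
  e2n <- edge_to_node(tree)
  intervals <- vector("list", length(ev) - 1L)
  prev_lin <- integer(0)
  for (k in seq_len(length(ev) - 1L)) {
    t0 <- ev[k]; t1 <- ev[k + 1L]
    mid <- (t0 + t1) / 2
    alive_e <- which(d[tree$edge[, 1]] <= mid & d[tree$edge[, 2]] >= mid)
    lin <- tree$edge[alive_e, 2]
    o <- order(lin)
    alive_e <- alive_e[o]; lin <- lin[o]
    parent <- ifelse(lin %in% prev_lin, NA_integer_, p[lin])
    n <- length(lin)
    reg <- if (is.null(regimes)) rep("A", n) else
      vapply(seq_len(n), function(ii)
        state_at(regimes$maps[[alive_e[ii]]], mid - d[tree$edge[alive_e[ii], 1]]),
        character(1))
    if (is.null(biogeo)) {
      A <- matrix(1, n, n)
    } else {
      pats <- vapply(seq_len(n), function(ii)
        state_at(biogeo$maps[[alive_e[ii]]], mid - d[tree$edge[alive_e[ii], 1]]),
        character(1))
      occ <- do.call(rbind, lapply(strsplit(pats, ""), function(x) as.numeric(x == "1")))
      A <- (occ %*% t(occ) > 0) * 1
      diag(A) <- 1
    }
    same <- outer(reg, reg, "==") * 1
    dsym <- rowSums(A * same)
    intervals[[k]] <- list(t0 = t0, t1 = t1, lineages = lin, parent = parent,
                           edges = alive_e, regime = reg, A = A, d = dsym)
    prev_lin <- lin
  }
  structure(list(times = ev, intervals = intervals, tree = tree,
                 ntip = ntip, T = T,
                 regimes = !is.null(regimes), biogeo = !is.null(biogeo)),
            class = "event_timeline")
}
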