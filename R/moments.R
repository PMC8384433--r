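# Closed-form tip moments for the lineage-independent families (BM, OU,
# EB), single- or two-regime. On an ultrametric tree with root state z0:
#
#   BM:  V_ij = sum over the shared root->MRCA path of sigma2(regime)*dur
#   EB:  V_ij = sigma0^2 * sum over shared segments of
#               (exp(r_seg*t2) - exp(r_seg*t1)) / r_seg   (duration as r->0)
#   OU (shared alpha and sigma2, regime optima):
#        V_ij = sigma2/(2*alpha) * exp(-alpha*d_ij) * (1 - exp(-2*alpha*t_mrca))
#        m_i  = theta_root*exp(-alpha*T)
#               + alpha * int_0^T theta(regime at t) * exp(-alpha*(T-t)) dt
#
# with t measured from the root and d_ij the patristic distance.

# Precompute the path structure shared by all closed-form evaluations.
closed_form_setup <- function(tree, regimes = NULL) {
  ntip <- length(tree$tip.label)
  d <- node_depths(tree)
  M <- ape::mrca(tree)
  diag(M) <- seq_len(ntip)
  alphabet <- if (is.null(regimes)) "A" else regimes$alphabet
  # per-edge segments in absolute time
  seg <- lapply(seq_len(nrow(tree$edge)), function(e) {
    t0 <- d[tree$edge[e, 1]]
    if (is.null(regimes)) {
      durs <- tree$edge.length[e]; labs <- alphabet[1]
    } else {
      durs <- unname(regimes$maps[[e]]); labs <- names(regimes$maps[[e]])
    }
    ends <- t0 + cumsum(durs)
    list(t0 = c(t0, ends[-length(ends)]), t1 = ends,
         g = match(labs, alphabet))
  })
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- edge_order_map(pre, tree)
  # per-regime accumulated path time a_g[node]
  nn <- ntip + tree$Nnode
  a <- matrix(0, nn, length(alphabet))
  for (k in seq_len(nrow(pre$edge))) {
    e <- o[k]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    a[v, ] <- a[u, ]
    s <- seg[[e]]
    for (gi in seq_along(alphabet)) {
      a[v, gi] <- a[v, gi] + sum((s$t1 - s$t0)[s$g == gi])
    }
  }
  root_g <- if (is.null(regimes)) 1L else match(regimes$root_state, alphabet)
  list(tree = tree, ntip = ntip, depths = d, T = tree_height(tree),
       M = M, alphabet = alphabet, seg = seg, a = a,
       pre_edges = o, root_g = root_g)
}

# (exp(r*t1)*(exp(r*dur)-1))/r with the r->0 limit handled analytically.
eb_segment_integral <- function(r, t0, t1) {
  if (abs(r) < 1e-12) return(t1 - t0)
  (exp(r * t1) - exp(r * t0)) / r
}

#' Closed-form tip moments for BM, OU and EB models
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param params Parameter list (see [model_params()]).
#' @param tree Validated `phylo`.
#' @param regimes Optional [regime_history()] for two-regime parameters.
#' @param cache Optional precomputed structure (internal; reused across
#'   likelihood evaluations during fitting).
#' @return List with `m` (tip means, named) and `V` (tip covariance).
#' @export
tip_moments_closed_form <- function(model, params, tree, regimes = NULL,
                                    cache = NULL) {
  cf <- cache %||% closed_form_setup(tree, regimes)
  ntip <- cf$ntip
  ab <- cf$alphabet
  p <- params
  per_regime <- function(x) {
    if (length(x) == 1L) rep(unname(x), length(ab)) else unname(x[ab])
  }
  m <- rep(unname(p$z0) %||% NA_real_, ntip)
  if (model == "BM") {
    s2 <- per_regime(p$sigma2)
    acc <- as.numeric(cf$a %*% s2)
    V <- matrix(acc[cf$M], ntip, ntip)
  } else if (model == "EB") {
    r <- per_regime(p$r)
    nn <- nrow(cf$a)
    F <- numeric(nn)
    tree <- cf$tree
    for (k in seq_along(cf$pre_edges)) {
      e <- cf$pre_edges[k]
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      s <- cf$seg[[e]]
      contrib <- 0
      for (ii in seq_along(s$g)) {
        contrib <- contrib + eb_segment_integral(r[s$g[ii]], s$t0[ii], s$t1[ii])
      }
      F[v] <- F[u] + contrib
    }
    V <- unname(p$sigma2) * matrix(F[cf$M], ntip, ntip)
  } else if (model == "OU") {
    alpha <- unname(p$alpha)
    s2 <- unname(p$sigma2)
    theta <- per_regime(p$theta %||% p$z0)
    tm <- matrix(cf$depths[cf$M], ntip, ntip)
    if (alpha < 1e-10) {
      V <- s2 * tm
      m <- rep(theta[cf$root_g], ntip)
    } else {
      T <- cf$T
      V <- s2 / (2 * alpha) * exp(-alpha * 2 * (T - tm)) * (1 - exp(-2 * alpha * tm))
      D <- ou_mean_design(cf, alpha)
      m <- as.numeric(D %*% theta)
    }
  } else stop_("closed-form moments exist only for BM, OU and EB")
  names(m) <- cf$tree$tip.label
  dimnames(V) <- list(cf$tree$tip.label, cf$tree$tip.label)
  list(m = m, V = V)
}

# Design matrix of the OU mean: m = D %*% theta, where column g accumulates
# exp(-alpha*(T-t2)) - exp(-alpha*(T-t1)) over the tip's path segments in
# regime g, and the root regime additionally carries exp(-alpha*T) (the
# root state is fixed at the root-regime optimum).
ou_mean_design <- function(cf, alpha) {
  tree <- cf$tree
  nn <- nrow(cf$a)
  T <- cf$T
  D <- matrix(0, nn, length(cf$alphabet))
  D[cf$ntip + 1L, cf$root_g] <- exp(-alpha * T)
  for (k in seq_along(cf$pre_edges)) {
    e <- cf$pre_edges[k]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    D[v, ] <- D[u, ]
    s <- cf$seg[[e]]
    w <- exp(-alpha * (T - s$t1)) - exp(-alpha * (T - s$t0))
    for (ii in seq_along(s$g)) D[v, s$g[ii]] <- D[v, s$g[ii]] + w[ii]
  }
  D[seq_len(cf$ntip), , drop = FALSE]
}
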