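# Continuous-time Markov (Mk) machinery for discrete regime states:
# all-rates-different generator, Felsenstein pruning likelihood, ML rate
# estimation, and Bollback-style stochastic character mapping with
# uniformized within-branch histories.

#' Build an all-rates-different Mk generator
#'
#' @param rates Numeric vector of off-diagonal transition rates, filled row
#'   by row (length `s*(s-1)` for `s` states); all `>= 0`.
#' @param states Character vector of state names.
#' @return An `s x s` generator matrix with rows summing to zero.
#' @export
mk_generator <- function(rates, states = c("tropical", "temperate", "both")) {
  s <- length(states)
  if (length(rates) != s * (s - 1)) stop_("need s*(s-1) transition rates")
  if (any(rates < 0)) stop_("transition rates must be non-negative")
  Q <- matrix(0, s, s, dimnames = list(states, states))
  Q[row(Q) != col(Q)] <- 0
  k <- 1L
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (i != j) { Q[i, j] <- rates[k]; k <- k + 1L }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Spectral transition-probability factory with a Pade fallback for
# defective generators. Returns function(t) -> P(t).
transition_prob_fun <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  Vi <- if (!is.null(e)) tryCatch(solve(e$vectors), error = function(err) NULL) else NULL
  ok <- !is.null(Vi) && all(is.finite(Mod(Vi)))
  if (ok) {
    function(t) {
      P <- Re(e$vectors %*% (exp(e$values * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

# Pruning pass. Returns per-node scaled conditional likelihood matrix L
# (rows nodes, cols states), the per-node log scaling factors, and the
# per-edge transition matrices.
mk_prune <- function(tree, tip_states, Q) {
  states <- rownames(Q)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  st <- tip_states[tree$tip.label]
  if (any(is.na(st))) stop_("every tip needs a state")
  if (!all(st %in% states)) stop_("tip state outside the model's state set")
  Pfun <- transition_prob_fun(Q)
  P <- lapply(tree$edge.length, Pfun)
  L <- matrix(0, nn, length(states), dimnames = list(NULL, states))
  L[cbind(seq_len(ntip), match(st, states))] <- 1
  logscale <- numeric(nn)
  po <- ape::reorder.phylo(tree, "postorder")
  o <- edge_order_map(po, tree)
  for (k in seq_len(nrow(po$edge))) {
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    contrib <- as.numeric(P[[o[k]]] %*% L[v, ])
    if (all(L[u, ] == 0)) L[u, ] <- contrib else L[u, ] <- L[u, ] * contrib
    logscale[u] <- logscale[u] + logscale[v]
    m <- max(L[u, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      L[u, ] <- L[u, ] / m
      logscale[u] <- logscale[u] + log(m)
    }
  }
  list(L = L, logscale = logscale, P = P, states = states)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree Validated `phylo`.
#' @param tip_states Named character vector of tip states.
#' @param Q Generator from [mk_generator()].
#' @param pi Root state frequencies: `"equal"` (default) or a numeric
#'   vector over the states.
#' @return Log-likelihood of the tip states.
#' @export
mk_loglik <- function(tree, tip_states, Q, pi = "equal") {
  pr <- mk_prune(tree, tip_states, Q)
  root <- length(tree$tip.label) + 1L
  pivec <- root_freqs(pi, ncol(pr$L))
  lik <- sum(pivec * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[root]
}

root_freqs <- function(pi, s) {
  if (identical(pi, "equal")) return(rep(1 / s, s))
  if (length(pi) != s || any(pi < 0)) stop_("invalid root frequencies")
  pi / sum(pi)
}

#' Fit a 3-state all-rates-different Mk model by maximum likelihood
#'
#' Transition rates between every ordered pair of states are free. When all
#' tips share one state the MLE sits on the zero-rate boundary; the fit is
#' then returned with `boundary = TRUE` and log-likelihood `log(pi_state)`
#' rather than raising an error.
#'
#' @param tree Validated `phylo`.
#' @param tip_states Named character vector of tip states.
#' @param states State alphabet (default tropical/temperate/both).
#' @param pi Root frequencies (see [mk_loglik()]).
#' @param n_starts Number of optimizer starts (default 2).
#' @return Object of class `mk_model`: `states`, `rates`, `Q`, `logLik`,
#'   `pi`, `boundary`, `convergence`.
#' @export
fit_mk <- function(tree, tip_states, states = c("tropical", "temperate", "both"),
                   pi = "equal", n_starts = 2) {
  tip_states <- tip_states[tree$tip.label]
  if (!all(tip_states %in% states)) stop_("tip state outside the state alphabet")
  s <- length(states)
  nrate <- s * (s - 1)
  pivec <- root_freqs(pi, s)
  if (length(unique(tip_states)) == 1L) {
    rates <- rep(0, nrate)
    Q <- mk_generator(rates, states)
    return(structure(list(states = states, rates = rates, Q = Q,
                          logLik = log(pivec[match(tip_states[1], states)]),
                          pi = pivec, boundary = TRUE, convergence = 0L),
                     class = "mk_model"))
  }
  tot <- sum(tree$edge.length)
  nll <- function(logr) {
    if (any(logr > 15)) return(1e10)
    Q <- mk_generator(exp(logr), states)
    ll <- mk_loglik(tree, tip_states, Q, pi = pivec)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- rep(log(max(s - 1, 1) / tot), nrate)
  best <- NULL
  for (k in seq_len(n_starts)) {
    start <- base + (k - 1) * stats::rnorm(nrate, 0, 0.5)
    op <- stats::optim(start, nll, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  rates <- exp(best$par)
  structure(list(states = states, rates = rates,
                 Q = mk_generator(rates, states),
                 logLik = -best$value, pi = pivec,
                 boundary = any(rates < 1e-8),
                 convergence = best$convergence),
            class = "mk_model")
}

#' Sample stochastic character maps
#'
#' Bollback-style sampling: conditional likelihoods from pruning give the
#' root and node state distributions; states are drawn node by node from
#' the root outward, and within-branch histories conditioned on the two
#' endpoint states are drawn by uniformization. Node-state frequencies over
#' a large map bank converge to the exact pruning-based conditionals.
#'
#' @param tree Validated `phylo`.
#' @param model An `mk_model` from [fit_mk()], or a generator matrix.
#' @param tip_states Named character vector of tip states.
#' @param n Number of maps (default 20).
#' @param seed Optional integer seed.
#' @param pi Root frequencies.
#' @return List of `n` [regime_history()] objects on the model's alphabet.
#' @export
sample_stochastic_maps <- function(tree, model, tip_states, n = 20,
                                   seed = NULL, pi = "equal") {
  Q <- if (inherits(model, "mk_model")) model$Q else model
  states <- rownames(Q)
  tip_states <- tip_states[tree$tip.label]
  pr <- mk_prune(tree, tip_states, Q)
  root <- length(tree$tip.label) + 1L
  pivec <- root_freqs(pi, length(states))
  rootp <- pivec * pr$L[root, ]
  if (sum(rootp) <= 0) stop_("no valid history: tip states have zero likelihood under the model")
  rootp <- rootp / sum(rootp)
  set_seed_if(seed)
  # preorder edges
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- edge_order_map(pre, tree)
  lapply(seq_len(n), function(rep_i) {
    node_state <- integer(length(tree$tip.label) + tree$Nnode)
    node_state[root] <- sample.int(length(states), 1, prob = rootp)
    maps <- vector("list", nrow(tree$edge))
    for (k in seq_len(nrow(pre$edge))) {
      e <- o[k]
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      w <- pr$P[[e]][node_state[u], ] * pr$L[v, ]
      if (sum(w) <= 0) stop_("no valid history along an edge (zero-rate model with conflicting tips?)")
      node_state[v] <- sample.int(length(states), 1, prob = w / sum(w))
      maps[[e]] <- sample_ctmc_bridge(Q, node_state[u], node_state[v],
                                      tree$edge.length[e], states)
    }
    regime_history(tree, maps, alphabet = states)
  })
}

# Endpoint-conditioned CTMC path by uniformization (Hobolth & Stone style).
# Returns a named duration vector, root-ward segment first.
sample_ctmc_bridge <- function(Q, a, b, t, states) {
  s <- nrow(Q)
  lambda <- max(-diag(Q))
  if (lambda <= 0 || t <= 0) {
    if (a != b) stop_("no valid history: zero-rate model with conflicting endpoint states")
    return(stats::setNames(t, states[a]))
  }
  R <- diag(s) + Q / lambda
  Pt <- transition_prob_fun(Q)(t)
  pab <- Pt[a, b]
  # sample the number of uniformized jumps
  Rpow <- list(diag(s))
  u <- stats::runif(1)
  cum <- 0; njump <- NA_integer_
  pois_log <- -lambda * t
  for (m in 0:1000) {
    if (m > 0) {
      Rpow[[m + 1L]] <- Rpow[[m]] %*% R
      pois_log <- pois_log + log(lambda * t) - log(m)
    }
    pm <- exp(pois_log) * Rpow[[m + 1L]][a, b] / pab
    cum <- cum + pm
    if (cum >= u) { njump <- m; break }
  }
  if (is.na(njump)) njump <- 1000L
  if (njump == 0L) return(stats::setNames(t, states[a]))
  # sample the uniformized chain states between the endpoints
  path <- integer(njump + 1L)
  path[1] <- a
  for (m in seq_len(njump)) {
    back <- Rpow[[njump - m + 1L]][, b]
    w <- R[path[m], ] * back
    path[m + 1L] <- if (m == njump) b else sample.int(s, 1, prob = w / sum(w))
  }
  jt <- sort(stats::runif(njump, 0, t))
  bounds <- c(0, jt, t)
  segs <- stats::setNames(diff(bounds), states[path])
  segs <- segs[segs > 0]
  if (!length(segs)) segs <- stats::setNames(t, states[a])
  merge_adjacent(segs)
}

#' Exact marginal node-state conditionals
#'
#' Marginal posterior distribution of the state at each internal node given
#' the tips, computed from the pruning pass (used as the convergence target
#' for stochastic-map banks).
#'
#' @inheritParams mk_loglik
#' @return Matrix (internal nodes x states) of conditional probabilities.
#' @export
mk_node_conditionals <- function(tree, tip_states, Q, pi = "equal") {
  states <- rownames(Q)
  s <- length(states)
  ntip <- length(tree$tip.label)
  pr <- mk_prune(tree, tip_states[tree$tip.label], Q)
  pivec <- root_freqs(pi, s)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  # outside (root-ward) partial likelihoods via preorder
  G <- matrix(0, nn, s)
  G[root, ] <- pivec
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- edge_order_map(pre, tree)
  for (k in seq_len(nrow(pre$edge))) {
    e <- o[k]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
    gu <- G[u, ]
    for (w in sibs) {
      ew <- which(tree$edge[, 2] == w)
      gu <- gu * as.numeric(pr$P[[ew]] %*% pr$L[w, ])
    }
    G[v, ] <- as.numeric(t(pr$P[[e]]) %*% gu)
    m <- max(G[v, ]); if (m > 0) G[v, ] <- G[v, ] / m
  }
  post <- G * pr$L
  post <- post / rowSums(post)
  out <- post[(ntip + 1L):nn, , drop = FALSE]
  colnames(out) <- states
  out
}
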