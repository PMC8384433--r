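# Forward simulation: Euler-Maruyama trait evolution under all six model
# families (single- or two-regime, with or without biogeography), plus the
# fixture generators (birth-death trees, Mk regime histories, area
# gain/loss biogeography) and observational-error injection.
#
# Per alive lineage and time step: X <- X + drift*dt + sqrt(rate*dt)*N(0,1),
# with drift 0 for BM/EB/DD, alpha*(theta_regime - X) for OU, and
# S_regime * (weighted sympatric same-regime mean - X) for MC. Diffusion
# rates: sigma2 (BM/MC), sigma0^2*exp(r_regime * t) (EB, time since root),
# sigma0^2*exp(r_regime * d_j) (DD_exp) and sigma0^2 + b_regime * d_j
# (DD_lin), where d_j counts the sympatric same-regime lineages including
# the focal one. At a branching both daughters copy the parent state.

#' Simulate trait evolution along a tree
#'
#' @param tree Validated `phylo`.
#' @param model Family name: `"BM"`, `"OU"`, `"EB"`, `"DDexp"`, `"DDlin"`
#'   or `"MC"`.
#' @param params Parameter list (see [model_params()]); two-regime
#'   parameters are named vectors over the regime alphabet.
#' @param regimes Optional [regime_history()] (two-regime models).
#' @param biogeo Optional [biogeo_history()]; absent means full sympatry.
#' @param dt Euler step (time units); default `T/1000`, and never larger
#'   than `T/100`.
#' @param seed Optional integer seed; identical seeds give identical traits.
#' @param n_rep Number of independent replicate datasets simulated in one
#'   vectorized pass (default 1).
#' @param interaction `"within"` restricts competitive interactions and
#'   diversity counts to same-regime sympatric lineages (as in the model
#'   definitions); `"across"` lets all sympatric lineages interact, the
#'   regime setting only the focal lineage's coefficient.
#' @param timeline Optional precomputed [build_event_timeline()].
#' @return For `n_rep = 1`, a [trait_data()] table of true tip means
#'   (`se2 = 0`); otherwise a `tips x n_rep` matrix with tip labels as row
#'   names.
#' @export
simulate_traits <- function(tree, model, params, regimes = NULL, biogeo = NULL,
                            dt = NULL, seed = NULL, n_rep = 1,
                            interaction = c("within", "across"),
                            timeline = NULL) {
  interaction <- match.arg(interaction)
  model <- match.arg(model, c("BM", "OU", "EB", "DDexp", "DDlin", "MC"))
  tl <- timeline %||% build_event_timeline(tree, regimes, biogeo)
  T <- tl$T
  dt <- dt %||% (T / 1000)
  if (dt <= 0 || dt > T / 100) stop_("dt must be positive and at most T/100")
  set_seed_if(seed)
  p <- params
  get2 <- function(x, reg) if (length(x) == 1L) rep(unname(x), length(reg)) else {
    if (is.null(names(x))) stop_("two-regime parameters must be named by regime")
    unname(x[reg])
  }
  X <- matrix(p$z0, 2, n_rep)
  cur <- tl$intervals[[1]]$lineages
  for (iv in tl$intervals) {
    # branching / bookkeeping: map rows onto this interval's lineage set
    idx <- match(iv$lineages, cur)
    grow <- which(is.na(idx))
    if (length(grow)) idx[grow] <- match(iv$parent[grow], cur)
    X <- X[idx, , drop = FALSE]
    cur <- iv$lineages
    n <- length(cur)
    reg <- iv$regime
    span <- iv$t1 - iv$t0
    if (span <= 0) next
    nst <- max(1L, ceiling(span / dt))
    h <- span / nst
    # interval-constant pieces
    if (model %in% c("DDexp", "DDlin")) {
      dsym <- if (interaction == "within") iv$d else rowSums(iv$A)
    }
    if (model == "MC") {
      S <- get2(p$S, reg)
      W <- iv$A * (if (interaction == "within") outer(reg, reg, "==") else 1)
      W <- W / rowSums(W)
    }
    rate <- switch(model,
      BM = get2(p$sigma2, reg),
      MC = rep(unname(p$sigma2), n),
      OU = rep(unname(p$sigma2), n),
      DDexp = unname(p$sigma2) * exp(get2(p$r, reg) * dsym),
      DDlin = unname(p$sigma2) + get2(p$b, reg) * dsym,
      EB = NULL)
    if (model == "DDlin" && any(rate < 0)) {
      stop_(sprintf("DD_lin rate is negative (%.4g) on interval [%.4g, %.4g] for lineage %d: parameters outside the admissible region",
                    min(rate), iv$t0, iv$t1, cur[which.min(rate)]))
    }
    for (s in seq_len(nst)) {
      tmid <- iv$t0 + (s - 0.5) * h
      if (model == "EB") rate <- unname(p$sigma2) * exp(get2(p$r, reg) * tmid)
      drift <- switch(model,
        OU = unname(p$alpha) * (get2(p$theta, reg) - X),
        MC = S * (W %*% X - X),
        NULL)
      noise <- matrix(stats::rnorm(n * n_rep), n, n_rep) * sqrt(rate * h)
      X <- X + noise + if (is.null(drift)) 0 else drift * h
    }
  }
  tips <- tl$tree$tip.label[cur]
  rownames(X) <- tips
  X <- X[tl$tree$tip.label, , drop = FALSE]
  if (n_rep == 1L) trait_data(rownames(X), as.numeric(X)) else X
}

#' Add observational error to true species means
#'
#' Observational error lumps the "known" sampling deviation of a species
#' mean (its squared standard error) with an "unknown" nuisance variance
#' (plasticity, instrument error): `observed_i = true_i +
#' N(0, se2_i + sigma2_err)`, independently across species.
#'
#' @param traits A [trait_data()] table of true means.
#' @param se2 Squared standard errors (scalar or per species).
#' @param sigma2_err Nuisance error variance (`>= 0`).
#' @param seed Optional integer seed.
#' @return A [trait_data()] table of observed means with the `se2` column
#'   set (the nuisance part is left to be estimated, as in fitting).
#' @export
add_observational_error <- function(traits, se2 = 0, sigma2_err = 0, seed = NULL) {
  se2 <- rep_len(se2, nrow(traits))
  if (any(se2 < 0) || sigma2_err < 0) stop_("error variances must be >= 0")
  set_seed_if(seed)
  obs <- traits$mean + stats::rnorm(nrow(traits), 0, sqrt(se2 + sigma2_err))
  trait_data(traits$species, obs, n = traits$n, se2 = se2)
}

#' Simulate a birth-death chronogram
#'
#' @param n_tips Number of extant tips (`>= 3`).
#' @param birth,death Speciation and extinction rates (per Myr).
#' @param seed Optional integer seed.
#' @param age Optional target root age (Myr); the tree is rescaled to this
#'   height after simulation.
#' @return An ultrametric `phylo` passing [validate_tree()].
#' @export
simulate_bd_tree <- function(n_tips, birth = 0.15, death = 0.05, seed = NULL,
                             age = NULL) {
  if (n_tips < 3) stop_("need at least 3 tips")
  if (birth <= 0 || death < 0) stop_("rates must be positive (birth) / non-negative (death)")
  set_seed_if(seed)
  tree <- NULL
  for (try in 1:50) {
    tree <- tryCatch(ape::rphylo(n_tips, birth, death), error = function(e) NULL)
    if (!is.null(tree)) break
  }
  if (is.null(tree)) stop_("birth-death simulation failed repeatedly")
  if (!is.null(age)) tree$edge.length <- tree$edge.length * (age / tree_height(tree))
  validate_tree(tree)
  tree
}

#' Simulate a regime history by forward Mk evolution
#'
#' @param tree Validated `phylo`.
#' @param Q Generator from [mk_generator()] (or an `mk_model`).
#' @param seed Optional integer seed.
#' @param root_state Root state name; sampled from `pi` when `NULL`.
#' @param pi Root frequencies.
#' @return A [regime_history()] on the generator's state set.
#' @export
simulate_regime_history <- function(tree, Q, seed = NULL, root_state = NULL,
                                    pi = "equal") {
  if (inherits(Q, "mk_model")) Q <- Q$Q
  states <- rownames(Q)
  set_seed_if(seed)
  pivec <- root_freqs(pi, length(states))
  root <- length(tree$tip.label) + 1L
  node_state <- integer(length(tree$tip.label) + tree$Nnode)
  node_state[root] <- if (is.null(root_state)) {
    sample.int(length(states), 1, prob = pivec)
  } else match(root_state, states)
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- edge_order_map(pre, tree)
  maps <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(pre$edge))) {
    e <- o[k]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sim <- sim_ctmc_forward(Q, node_state[u], tree$edge.length[e], states)
    maps[[e]] <- sim$segs
    node_state[v] <- sim$end
  }
  regime_history(tree, maps, alphabet = states)
}

sim_ctmc_forward <- function(Q, a, t, states) {
  segs <- numeric(0); labs <- character(0)
  cur <- a; left <- t
  repeat {
    rate <- -Q[cur, cur]
    wait <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (wait >= left) {
      segs <- c(segs, left); labs <- c(labs, states[cur])
      break
    }
    segs <- c(segs, wait); labs <- c(labs, states[cur])
    left <- left - wait
    w <- Q[cur, ]; w[cur] <- 0
    cur <- sample.int(length(states), 1, prob = w)
  }
  list(segs = merge_adjacent(stats::setNames(segs, labs)), end = cur)
}

#' Simulate a biogeographic occupancy history
#'
#' Each lineage gains absent areas at rate `gain` and loses occupied areas
#' at rate `loss` per area, with loss suppressed while only one area is
#' occupied (a lineage always occupies at least one area). Daughters
#' inherit the parent's occupancy at branching.
#'
#' @param tree Validated `phylo`.
#' @param K Number of areas (`>= 1`).
#' @param gain,loss Per-area gain and loss rates (per Myr).
#' @param seed Optional integer seed.
#' @param root_occupancy Logical/0-1 vector of length `K` for the root, or
#'   `NULL` to start in one uniformly chosen area.
#' @param areas Area names (default `area1..areaK`).
#' @return A [biogeo_history()].
#' @export
simulate_biogeo_history <- function(tree, K, gain = 0.02, loss = 0.02,
                                    seed = NULL, root_occupancy = NULL,
                                    areas = paste0("area", seq_len(K))) {
  if (K < 1) stop_("need K >= 1 areas")
  if (gain < 0 || loss < 0) stop_("rates must be >= 0")
  set_seed_if(seed)
  occ0 <- if (is.null(root_occupancy)) {
    z <- rep(0, K); z[sample.int(K, 1)] <- 1; z
  } else as.numeric(root_occupancy != 0)
  if (sum(occ0) < 1) stop_("root must occupy at least one area")
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- edge_order_map(pre, tree)
  root <- length(tree$tip.label) + 1L
  node_occ <- vector("list", length(tree$tip.label) + tree$Nnode)
  node_occ[[root]] <- occ0
  maps <- vector("list", nrow(tree$edge))
  pat <- function(occ) paste(occ, collapse = "")
  for (k in seq_len(nrow(pre$edge))) {
    e <- o[k]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    occ <- node_occ[[u]]
    left <- tree$edge.length[e]
    segs <- numeric(0); labs <- character(0)
    repeat {
      can_lose <- sum(occ) > 1
      rates <- ifelse(occ == 1, if (can_lose) loss else 0, gain)
      tot <- sum(rates)
      wait <- if (tot > 0) stats::rexp(1, tot) else Inf
      if (wait >= left) {
        segs <- c(segs, left); labs <- c(labs, pat(occ))
        break
      }
      segs <- c(segs, wait); labs <- c(labs, pat(occ))
      left <- left - wait
      j <- sample.int(K, 1, prob = rates)
      occ[j] <- 1 - occ[j]
    }
    maps[[e]] <- merge_adjacent(stats::setNames(segs, labs))
    node_occ[[v]] <- occ
  }
  biogeo_history(tree, maps, areas = areas)
}
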