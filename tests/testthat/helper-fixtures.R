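# Fixture builders shared across test files. Everything is generated in
# code from fixed seeds; no data files.

two_state <- c("tropical", "temperate")

# Random small fixture: ultrametric tree + 2-state regime history
# (+ optional 2-area biogeography), sized for exactness checks.
random_fixture <- function(seed, n_tips = 10, with_biogeo = FALSE, age = NULL) {
  tree <- simulate_bd_tree(n_tips, 0.3, 0.1, seed = derive_seed(seed, 1),
                           age = age)
  Q <- mk_generator(c(0.08, 0.05), two_state)
  regimes <- simulate_regime_history(tree, Q, seed = derive_seed(seed, 2),
                                     root_state = "tropical")
  biogeo <- if (with_biogeo) {
    simulate_biogeo_history(tree, K = 2, gain = 0.06, loss = 0.08,
                            seed = derive_seed(seed, 3))
  } else NULL
  list(tree = tree, regimes = regimes, biogeo = biogeo)
}

# Brute-force Mk likelihood: sum over all internal-node state assignments.
mk_loglik_enum <- function(tree, tip_states, Q, pi = rep(1 / nrow(Q), nrow(Q))) {
  states <- rownames(Q)
  s <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  tipidx <- match(tip_states[tree$tip.label], states)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nint)))
  for (gi in seq_len(nrow(grid))) {
    assign_state <- c(tipidx, grid[gi, ])
    lik <- pi[assign_state[root]]
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      lik <- lik * P[[e]][assign_state[u], assign_state[v]]
    }
    total <- total + lik
  }
  log(total)
}

# Monte-Carlo standard errors for tip moment checks.
mc_se_mean <- function(V, R) sqrt(diag(V) / R)
mc_se_var <- function(V, R) sqrt(2 / (R - 1)) * diag(V)
mc_se_cov <- function(V, R) sqrt((outer(diag(V), diag(V)) + V^2) / (R - 1))
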