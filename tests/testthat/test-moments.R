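# Closed-form and propagated tip moments, and the observational-error
# multivariate-normal likelihood.

test_that("BM covariances are shared path lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  mo <- tip_moments_closed_form("BM", model_params(z0 = 0, sigma2 = 1), tr)
  expect_equal(mo$V["A", "A"], 2)
  expect_equal(mo$V["A", "B"], 1)
  expect_equal(mo$V["A", "C"], 0)
  expect_equal(unname(mo$m), c(0, 0, 0))
  # against ape's independent BM covariance
  fx <- random_fixture(3, n_tips = 9)
  mo2 <- tip_moments_closed_form("BM", model_params(z0 = 0, sigma2 = 2), fx$tree)
  expect_equal(mo2$V, 2 * ape::vcv(fx$tree)[rownames(mo2$V), colnames(mo2$V)],
               tolerance = 1e-10)
})

test_that("EB reduces to BM at r = 0 and matches the rate integral", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  bm <- tip_moments_closed_form("BM", model_params(z0 = 0, sigma2 = 1), tr)
  eb0 <- tip_moments_closed_form("EB", model_params(z0 = 0, sigma2 = 1, r = 0), tr)
  expect_equal(eb0$V, bm$V, tolerance = 1e-12)
  eb <- tip_moments_closed_form("EB", model_params(z0 = 0, sigma2 = 1, r = -0.5), tr)
  expect_equal(eb$V["C", "C"], (1 - exp(-1)) / 0.5, tolerance = 1e-12)
  # quadrature oracle for a two-regime variance
  fx <- random_fixture(4, n_tips = 6)
  r <- c(tropical = -0.3, temperate = -0.1)
  ebt <- tip_moments_closed_form("EB", model_params(z0 = 0, sigma2 = 1, r = r),
                                 fx$tree, fx$regimes)
  tip <- fx$tree$tip.label[1]
  segs <- shared_path_segments(fx$tree, fx$regimes, tip, tip)
  oracle <- sum(vapply(seq_len(nrow(segs)), function(i) {
    stats::integrate(function(t) exp(r[[segs$regime[i]]] * t),
                     segs$t0[i], segs$t1[i], rel.tol = 1e-12)$value
  }, numeric(1)))
  expect_equal(ebt$V[tip, tip], oracle, tolerance = 1e-8)
})

test_that("OU moments match the fixed-root formulas and the BM limit", {
  fx <- random_fixture(8, n_tips = 6)
  tr <- fx$tree
  T <- tree_height(tr)
  alpha <- 0.8; s2 <- 1.3
  mo <- tip_moments_closed_form("OU", model_params(z0 = 1, sigma2 = s2,
                                                   alpha = alpha, theta = 1), tr)
  expect_equal(unname(diag(mo$V)), rep(s2 / (2 * alpha) * (1 - exp(-2 * alpha * T)), 6),
               tolerance = 1e-10)
  tm <- ape::vcv(tr)[rownames(mo$V), colnames(mo$V)]
  expect_equal(mo$V, s2 / (2 * alpha) * exp(-2 * alpha * (T - tm)) *
                 (1 - exp(-2 * alpha * tm)), tolerance = 1e-10)
  # alpha -> 0 limit taken analytically
  bm <- tip_moments_closed_form("BM", model_params(z0 = 1, sigma2 = s2), tr)
  ou0 <- tip_moments_closed_form("OU", model_params(z0 = 1, sigma2 = s2,
                                                    alpha = 0, theta = 1), tr)
  expect_equal(ou0$V, bm$V, tolerance = 1e-10)
  expect_equal(ou0$m, bm$m)
  # two-regime mean: weights along each tip path integrate to one
  th <- c(tropical = 2, temperate = 5)
  mo2 <- tip_moments_closed_form("OU", model_params(z0 = 2, sigma2 = s2,
                                                    alpha = alpha, theta = th),
                                 tr, fx$regimes)
  expect_true(all(mo2$m >= min(th) - 1e-8 & mo2$m <= max(th) + 1e-8))
  D <- compevol:::ou_mean_design(compevol:::closed_form_setup(tr, fx$regimes), alpha)
  expect_equal(unname(rowSums(D)), rep(1, 6), tolerance = 1e-10)
})

test_that("MC propagation matches the two-lineage closed form exactly", {
  tr2 <- parse_newick("(A:2,B:2);")
  tl <- build_event_timeline(tr2)
  s2 <- 0.5
  for (S in c(-0.4, 0.4)) {
    mo <- tip_moments_ode("MC", model_params(z0 = 0, sigma2 = s2, S = S), tl)
    vd <- mo$V["A", "A"] + mo$V["B", "B"] - 2 * mo$V["A", "B"]
    # the trait difference is OU with pull -S toward zero (repulsion S < 0
    # reverses the pull, the same expression continues analytically)
    expect_equal(vd, (s2 / S) * (1 - exp(-2 * S * 2)), tolerance = 1e-8)
  }
  # attraction case in the spec's |S| form
  mo <- tip_moments_ode("MC", model_params(z0 = 0, sigma2 = s2, S = 0.4), tl)
  vd <- mo$V["A", "A"] + mo$V["B", "B"] - 2 * mo$V["A", "B"]
  expect_equal(vd, (s2 / abs(0.4)) * (1 - exp(-2 * abs(0.4) * 2)), tolerance = 1e-8)
})

test_that("MC with S = 0 nests BM through the timeline machinery", {
  fx <- random_fixture(5, n_tips = 8)
  tl <- build_event_timeline(fx$tree, fx$regimes)
  mc <- tip_moments_ode("MC", model_params(z0 = 0.7, sigma2 = 1.2,
                                           S = c(tropical = 0, temperate = 0)), tl)
  bm <- tip_moments_closed_form("BM", model_params(z0 = 0.7, sigma2 = 1.2), fx$tree)
  expect_equal(mc$V, bm$V[rownames(mc$V), colnames(mc$V)], tolerance = 1e-6)
  expect_equal(mc$m, bm$m[names(mc$m)])
})

test_that("DD_exp variance equals the per-epoch rate sum under full sympatry", {
  tr <- simulate_bd_tree(8, 0.3, 0.1, seed = 5)
  tl <- build_event_timeline(tr)
  r <- -0.1
  mo <- tip_moments_ode("DDexp", model_params(z0 = 0, sigma2 = 1, r = r), tl)
  T <- tree_height(tr)
  depths <- sort(T - ape::branching.times(tr))  # 0 = root split
  nlin <- 1 + seq_along(depths)
  oracle <- sum(exp(r * nlin) * diff(c(depths, T)))
  expect_equal(unname(diag(mo$V)), rep(oracle, 8), tolerance = 1e-8)
})

test_that("the MC integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  fx <- random_fixture(7, n_tips = 8, with_biogeo = TRUE)
  tl <- build_event_timeline(fx$tree, fx$regimes, fx$biogeo)
  p <- model_params(z0 = 0, sigma2 = 1, S = c(tropical = -0.3, temperate = -0.1))
  mine <- tip_moments_ode("MC", p, tl)$V
  # reference: deSolve ode45 over the same piecewise-constant system
  V <- matrix(0, 2, 2); lin <- tl$intervals[[1]]$lineages
  for (iv in tl$intervals) {
    idx <- match(iv$lineages, lin)
    g <- which(is.na(idx)); idx[g] <- match(iv$parent[g], lin)
    V <- V[idx, idx, drop = FALSE]; lin <- iv$lineages
    n <- length(lin); reg <- iv$regime
    W <- iv$A * outer(reg, reg, "=="); W <- W / rowSums(W)
    Svec <- unname(p$S[reg])
    R <- Svec * (W - diag(n))
    f <- function(t, y, parms) {
      M <- matrix(y, n, n)
      list(as.numeric(R %*% M + M %*% t(R) + diag(1, n)))
    }
    out <- deSolve::ode(as.numeric(V), c(0, iv$t1 - iv$t0), f, NULL,
                        method = "ode45", rtol = 1e-10, atol = 1e-12)
    V <- matrix(out[2, -1], n, n)
  }
  rownames(V) <- colnames(V) <- fx$tree$tip.label[lin]
  expect_equal(mine, V[rownames(mine), colnames(mine)], tolerance = 1e-5)
})

test_that("full-sympatry biogeography matches no biogeography for DD and MC", {
  fx <- random_fixture(12, n_tips = 7)
  tr <- fx$tree
  ones <- lapply(seq_len(nrow(tr$edge)), function(e)
    stats::setNames(tr$edge.length[e], "11"))
  bio_full <- biogeo_history(tr, ones, areas = c("a", "b"))
  for (model in c("MC", "DDexp", "DDlin")) {
    p <- switch(model,
      MC = model_params(z0 = 0, sigma2 = 1, S = c(tropical = -0.2, temperate = -0.1)),
      DDexp = model_params(z0 = 0, sigma2 = 1, r = c(tropical = -0.15, temperate = -0.05)),
      DDlin = model_params(z0 = 0, sigma2 = 1, b = c(tropical = -0.05, temperate = -0.02)))
    a <- tip_moments_ode(model, p, build_event_timeline(tr, fx$regimes, bio_full))
    b <- tip_moments_ode(model, p, build_event_timeline(tr, fx$regimes))
    expect_equal(a$V, b$V, tolerance = 1e-6)
  }
})

test_that("single-area biogeography is equivalent to full sympatry", {
  fx <- random_fixture(13, n_tips = 6)
  bio1 <- simulate_biogeo_history(fx$tree, K = 1, seed = 4)
  p <- model_params(z0 = 0, sigma2 = 1, r = c(tropical = -0.1, temperate = -0.05))
  a <- tip_moments_ode("DDexp", p, build_event_timeline(fx$tree, fx$regimes, bio1))
  b <- tip_moments_ode("DDexp", p, build_event_timeline(fx$tree, fx$regimes))
  expect_equal(a$V, b$V, tolerance = 1e-10)
})

test_that("propagated covariances are symmetric positive semidefinite", {
  for (seed in c(3, 9)) {
    fx <- random_fixture(seed, n_tips = 10, with_biogeo = TRUE)
    tl <- build_event_timeline(fx$tree, fx$regimes, fx$biogeo)
    for (model in c("MC", "DDexp")) {
      p <- if (model == "MC") {
        model_params(z0 = 0, sigma2 = 1, S = c(tropical = -0.4, temperate = -0.1))
      } else {
        model_params(z0 = 0, sigma2 = 1, r = c(tropical = -0.2, temperate = -0.1))
      }
      V <- tip_moments_ode(model, p, tl)$V
      expect_lt(max(abs(V - t(V))), 1e-10)
      expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("the log-likelihood matches a dense normal oracle and is order-invariant", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  y <- c(A = 0, B = 0, C = 0)
  td <- trait_data(names(y), y)
  sp <- model_spec("BM")
  p <- model_params(z0 = 0, sigma2 = 1)
  ll <- log_likelihood(sp, p, tr, traits = td)
  V <- tip_moments_closed_form("BM", p, tr)$V
  oracle <- -0.5 * (3 * log(2 * pi) + as.numeric(determinant(V)$modulus) +
                      drop(t(y) %*% solve(V) %*% y))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # permuting species rows leaves the value unchanged
  td2 <- td[c(3, 1, 2), ]
  expect_equal(log_likelihood(sp, p, tr, traits = td2), ll, tolerance = 1e-12)
  # observational error inflates the diagonal
  td3 <- trait_data(names(y), y, se2 = 0.5)
  ll3 <- log_likelihood(sp, model_params(z0 = 0, sigma2 = 1, sigma2_err = 0.25),
                        tr, traits = td3)
  V3 <- V + diag(0.75, 3)
  oracle3 <- -0.5 * (3 * log(2 * pi) + as.numeric(determinant(V3)$modulus))
  expect_equal(ll3, oracle3, tolerance = 1e-10)
  # singular covariance is reported
  tr0 <- parse_newick("((A:0,B:0):2,C:2);")
  expect_error(log_likelihood(sp, model_params(z0 = 0, sigma2 = 1), tr0,
                              traits = td), "singular")
})
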