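# AICc machinery, the simpler-model selection rule, fitting, averaging over
# maps, derived metrics.

test_that("AICc and Akaike weights follow the standard formulas", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46)
  expect_error(aicc(-100, 3, 4), "n > k")
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(exp(0), exp(-1)) / (exp(0) + exp(-1)), tolerance = 1e-9)
  expect_equal(round(w, 5), c(0.73106, 0.26894))
  # invariant to a common logLik shift at fixed k, n
  a1 <- aicc(c(-10, -12), 3, 30); a2 <- aicc(c(-10, -12) + 7, 3, 30)
  expect_equal(akaike_weights(a1), akaike_weights(a2))
  expect_equal(sum(akaike_weights(c(3, 9, 4.4, 100))), 1)
})

test_that("select_best applies the simpler-model rule iteratively", {
  tbl <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(model = letters[seq_len(nrow(m))], k = m[, 1], AICc = m[, 2])
  }
  expect_equal(select_best(tbl(2, 100, 3, 99)), "a")    # simpler within 2
  expect_equal(select_best(tbl(2, 100, 3, 90)), "b")    # simpler too far
  expect_equal(select_best(tbl(3, 100, 3, 99)), "b")    # equal k: lower AICc
  # iterative application down a chain of simpler models
  expect_equal(select_best(tbl(4, 100, 3, 100.5, 2, 101.5)), "c")
  # but never a model >= 2 AICc above the minimum
  x <- tbl(3, 100, 2, 101.5, 1, 103.4)
  best <- select_best(x)
  expect_lt(x$AICc[x$model == best] - min(x$AICc), 2)
  expect_equal(best, "b")
})

test_that("select_best honors its invariant on random tables", {
  set.seed(99)
  for (i in 1:50) {
    tb <- data.frame(model = paste0("m", 1:5),
                     k = sample(2:6, 5, replace = TRUE),
                     AICc = round(runif(5, 100, 110), 2))
    best <- select_best(tb)
    expect_lt(tb$AICc[tb$model == best] - min(tb$AICc), 2)
  }
})

test_that("the BM MLE equals the closed-form GLS estimate", {
  fx <- random_fixture(21, n_tips = 30)
  p <- model_params(z0 = 2, sigma2 = 0.5)
  td <- simulate_traits(fx$tree, "BM", p, seed = 8)
  fit <- fit_model(model_spec("BM"), fx$tree, traits = td)
  C <- ape::vcv(fx$tree)[td$species, td$species]
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  z0_gls <- drop(one %*% Ci %*% td$mean) / drop(one %*% Ci %*% one)
  r <- td$mean - z0_gls
  s2_gls <- drop(r %*% Ci %*% r) / nrow(C)
  expect_equal(fit$params$z0, z0_gls, tolerance = 1e-4)
  expect_equal(fit$params$sigma2, s2_gls, tolerance = 1e-4)
})

test_that("the maximized likelihood is at least the truth's likelihood", {
  fx <- random_fixture(22, n_tips = 20)
  p <- model_params(z0 = 0, sigma2 = 0.5, r = c(tropical = -0.3, temperate = -0.1))
  td <- simulate_traits(fx$tree, "EB", p, fx$regimes, seed = 4)
  sp <- model_spec("EB", 2)
  fit <- fit_model(sp, fx$tree, fx$regimes, traits = td,
                   options = list(min_tips = 5, min_tips_per_regime = 2))
  ll_true <- log_likelihood(sp, p, fx$tree, fx$regimes, traits = td)
  expect_gte(fit$logLik, ll_true - 1e-6)
})

test_that("fitting with estimated observational error adds a parameter", {
  fx <- random_fixture(23, n_tips = 25)
  p <- model_params(z0 = 0, sigma2 = 0.5)
  td0 <- simulate_traits(fx$tree, "BM", p, seed = 2)
  td <- add_observational_error(td0, se2 = 0.2, sigma2_err = 0.3, seed = 3)
  sp0 <- model_spec("BM", error = "none")
  sp1 <- model_spec("BM", error = "estimate")
  expect_equal(sp0$k, 2); expect_equal(sp1$k, 3)
  f1 <- fit_model(sp1, fx$tree, traits = td)
  expect_gte(f1$params$sigma2_err, 0)
  expect_equal(f1$k, 3)
  # error model cannot fit worse than the fixed-zero-error model at its MLE
  f0 <- fit_model(sp0, fx$tree, traits = td)
  expect_gte(f1$logLik, f0$logLik - 1e-6)
})

test_that("free-parameter counts follow the model table", {
  want <- c(BM = 2, OU = 3, EB = 3, DDexp = 3, DDlin = 3, MC = 3)
  for (fam in names(want)) {
    expect_equal(model_spec(fam, 1)$k, unname(want[fam]))
    expect_equal(model_spec(fam, 2)$k, unname(want[fam]) + 1)
    expect_equal(model_spec(fam, 2, error = "estimate")$k, unname(want[fam]) + 2)
  }
})

test_that("two-regime fits enforce the per-regime tip floor", {
  fx <- random_fixture(30, n_tips = 12)
  td <- simulate_traits(fx$tree, "BM", model_params(z0 = 0, sigma2 = 1), seed = 1)
  expect_error(fit_model(model_spec("BM", 2), fx$tree, fx$regimes, traits = td),
               "each regime")
  expect_error(fit_model(model_spec("BM", 2), fx$tree, NULL, traits = td),
               "regime history")
})

test_that("aggregation over maps averages weights and reports the modal best", {
  mk_cmp <- function(w, aic, best) {
    tbl <- data.frame(model = c("BM_single", "MC_single"),
                      logLik = c(-10, -9), k = c(2, 3), n = 50,
                      AICc = aic, convergence = TRUE, weight = w)
    attr(tbl, "fits") <- list(
      BM_single = list(params = list(z0 = 1, sigma2 = 2)),
      MC_single = list(params = list(z0 = 1, sigma2 = 2, S = -0.1)))
    attr(tbl, "best") <- best
    class(tbl) <- c("model_comparison", "data.frame")
    tbl
  }
  agg <- aggregate_over_maps(list(mk_cmp(c(0.6, 0.4), c(100, 101), "MC_single"),
                                  mk_cmp(c(0.4, 0.6), c(101, 100), "MC_single"),
                                  mk_cmp(c(0.9, 0.1), c(99, 104), "BM_single")))
  expect_equal(agg$table$weight, c(mean(c(0.6, 0.4, 0.9)), mean(c(0.4, 0.6, 0.1))))
  expect_equal(agg$best, "MC_single")
  single <- aggregate_over_maps(list(mk_cmp(c(0.6, 0.4), c(100, 101), "BM_single")))
  expect_equal(single$table$weight, c(0.6, 0.4))
  bad <- mk_cmp(c(1, 0), c(1, 2), "BM_single"); bad$model <- c("BM_single", "EB_single")
  expect_error(aggregate_over_maps(list(mk_cmp(c(1, 0), c(1, 2), "BM_single"), bad)),
               "inconsistent")
})

test_that("support indices follow the quoted ratios", {
  w6 <- stats::setNames(rep(1 / 6, 6),
                        c("BM_single", "OU_single", "EB_single",
                          "DDexp_single", "DDlin_single", "MC_single"))
  expect_equal(competition_support_index(w6), 0.5)
  w6b <- w6; w6b["MC_single"] <- 0.5; w6b[setdiff(names(w6), "MC_single")] <- 0.1
  expect_equal(competition_support_index(w6b), 0.5 / 0.6)
  expect_error(competition_support_index(w6[1:3]), "missing")

  w12 <- stats::setNames(rep(1 / 12, 12), c(names(w6), paste0(sub("_single", "", names(w6)), "_two")))
  expect_equal(two_regime_support_index(w12), 0)
  w12b <- w12; w12b["MC_two"] <- 0.3
  expect_equal(two_regime_support_index(w12b), 0.3 / (0.3 + 1 / 12) - 0.5)
})

test_that("derived parameter ratios and rates at present are as defined", {
  expect_equal(ln_abs_ratio(c(tropical = -0.2, temperate = -0.2)), 0)
  expect_equal(ln_abs_ratio(c(tropical = -0.5, temperate = -0.1)), log(5))
  expect_error(ln_abs_ratio(c(a = 1, b = 2)), "regimes")

  fake_fit <- function(fam, params, T = 10, d_present = NULL, n = 50) {
    structure(list(spec = model_spec(fam), params = params, n = n,
                   info = list(T = T, d_present = d_present)),
              class = "fit_result")
  }
  expect_equal(rate_at_present(fake_fit("BM", model_params(z0 = 0, sigma2 = 2))), 2)
  expect_equal(rate_at_present(fake_fit("EB", model_params(z0 = 0, sigma2 = 2, r = 0))), 2)
  expect_equal(rate_at_present(fake_fit("EB", model_params(z0 = 0, sigma2 = 2, r = -0.1))),
               2 * exp(-1))
  expect_equal(rate_at_present(fake_fit("DDexp",
                                        model_params(z0 = 0, sigma2 = 2, r = -0.01),
                                        d_present = c(A = 30))),
               2 * exp(-0.3))
  expect_equal(rate_at_present(fake_fit("DDlin",
                                        model_params(z0 = 0, sigma2 = 2, b = -0.01),
                                        d_present = c(A = 30))),
               2 - 0.3)
  td <- trait_data(c("a", "b"), c(0, 1), se2 = c(0.1, 0.3))
  f <- fake_fit("BM", model_params(z0 = 0, sigma2 = 1, sigma2_err = 0.05))
  expect_equal(total_error(f, td), 0.05 + 0.2)
})

test_that("fitting is deterministic given data and seed", {
  fx <- random_fixture(31, n_tips = 15)
  td <- simulate_traits(fx$tree, "MC",
                        model_params(z0 = 0, sigma2 = 0.5,
                                     S = c(tropical = -0.3, temperate = -0.1)),
                        fx$regimes, seed = 2)
  o <- list(min_tips = 5, min_tips_per_regime = 3, seed = 11, n_starts = 2)
  f1 <- fit_model(model_spec("MC", 2), fx$tree, fx$regimes, traits = td, options = o)
  f2 <- fit_model(model_spec("MC", 2), fx$tree, fx$regimes, traits = td, options = o)
  expect_equal(f1$params, f2$params)
  expect_equal(f1$logLik, f2$logLik)
})
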