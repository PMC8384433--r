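# Maximum-likelihood fitting, AICc model selection, stochastic-map
# averaging and derived metrics.
#
# The optimizer works on a reduced parameter space: the mean (z0, or the
# two OU optima) is always profiled out by GLS, and when the data carry no
# observational error the overall rate scale is profiled analytically as
# well (every family's covariance is proportional to its rate parameter,
# with DD_lin handled through the slope-to-rate ratio b/sigma2). The
# remaining nonlinear parameters (slopes, S, alpha) are maximized by a
# bracketed 1-D search or Nelder-Mead with multiple starts. Variances are
# optimized on the log scale; by default the MC coefficient is constrained
# to repulsion (S <= 0) via S = -exp(psi), with an opt-in for attraction.

# ---- information criteria -------------------------------------------------

#' Small-sample corrected AIC
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of tips with data; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-100, 3, 50)  # 206 + 24/46
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop_("AICc undefined: need n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' @param aicc_values Numeric vector of AICc values (one per model).
#' @return Weights `exp(-delta/2)` normalized to sum to one.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Best-fit model under the simpler-model AICc rule
#'
#' The best model is the one with the lowest AICc, unless a model with
#' fewer parameters lies within 2 AICc units of the minimum, in which case
#' the simpler model supersedes it; the rule is applied iteratively until
#' no simpler candidate remains. Ties among equal-k candidates are broken
#' by lower AICc, then lexicographic model name.
#'
#' @param comparison Data frame with columns `model`, `k`, `AICc` (e.g.
#'   from [compare_models()]); rows flagged unusable (`convergence` FALSE)
#'   are ignored.
#' @return The selected model name.
#' @export
select_best <- function(comparison) {
  tbl <- as.data.frame(comparison)
  if ("convergence" %in% names(tbl)) tbl <- tbl[tbl$convergence, , drop = FALSE]
  if (nrow(tbl) < 1L) stop_("no usable fits")
  cand <- tbl[tbl$AICc - min(tbl$AICc) < 2, , drop = FALSE]
  cur <- which.min(cand$AICc)
  repeat {
    simpler <- which(cand$k < cand$k[cur])
    if (!length(simpler)) break
    o <- simpler[order(cand$AICc[simpler], cand$k[simpler], cand$model[simpler])]
    cur <- o[1]
  }
  cand$model[cur]
}

# ---- fitting --------------------------------------------------------------

# Coarse-grid + bracketed refinement for 1-D profiles (interaction
# likelihoods can be multimodal near constraint boundaries).
opt1d <- function(f, lo, hi, n_grid = 13) {
  xs <- seq(lo, hi, length.out = n_grid)
  fx <- vapply(xs, f, numeric(1))
  i <- which.min(fx)
  lo2 <- xs[max(1, i - 1)]; hi2 <- xs[min(n_grid, i + 1)]
  op <- stats::optimize(f, interval = c(lo2, hi2), tol = 1e-9)
  if (fx[i] < op$objective) list(par = xs[i], value = fx[i], convergence = 0L)
  else list(par = op$minimum, value = op$objective, convergence = 0L)
}

optnd <- function(f, starts) {
  best <- NULL
  for (st in starts) {
    op <- stats::optim(st, f, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-8))
    if (is.null(best) || op$value < best$value) best <- op
  }
  list(par = best$par, value = best$value, convergence = best$convergence)
}

#' Fit a model of trait evolution by maximum likelihood
#'
#' @param spec A [model_spec()].
#' @param tree Validated `phylo` with at least `min_tips` tips.
#' @param regimes [regime_history()] (required when `spec$n_regimes == 2`).
#' @param biogeo [biogeo_history()] (used when `spec$biogeo`).
#' @param traits [trait_data()] covering every tip.
#' @param interaction See [tip_moments_ode()].
#' @param options List of optionals: `n_starts` (default 4, including a
#'   BM-moment-matched start), `seed` (for the randomized starts),
#'   `min_tips` (default 10), `min_tips_per_regime` (default 10),
#'   `allow_attraction` (default `FALSE`: MC constrained to repulsion),
#'   `rk_h` (MC integrator control).
#' @return Object of class `fit_result`: `model`, `spec`, `params` (full
#'   MLE), `logLik`, `k`, `n`, `AICc`, `convergence`, `info`.
#' @export
fit_model <- function(spec, tree, regimes = NULL, biogeo = NULL, traits,
                      interaction = "within", options = list()) {
  op <- utils::modifyList(
    list(n_starts = 4, seed = NULL, min_tips = 10, min_tips_per_regime = 10,
         allow_attraction = FALSE, rk_h = 0.02), options)
  tr <- align_traits(traits, tree)
  n <- nrow(tr)
  if (n < op$min_tips) stop_(sprintf("need at least %d tips", op$min_tips))
  reg <- if (spec$n_regimes == 2) regimes else NULL
  if (spec$n_regimes == 2) {
    if (is.null(regimes)) stop_("two-regime fit requires a regime history")
    cnt <- table(tip_states(regimes))
    if (length(cnt) < 2 || any(cnt < op$min_tips_per_regime)) {
      stop_(sprintf("two-regime fit requires at least %d tips in each regime",
                    op$min_tips_per_regime))
    }
  }
  y <- tr$mean
  err <- tr$se2
  estimate_err <- spec$error == "estimate"
  profiled_scale <- !estimate_err && all(err == 0)
  fam <- spec$family

  # precomputed structures shared by all likelihood evaluations
  cache <- list()
  if (fam %in% c("BM", "OU", "EB")) {
    cf <- closed_form_setup(tree, reg)
    cache$closed <- cf
    ab <- cf$alphabet
    if (fam == "BM") {
      cache$Tg <- lapply(seq_along(ab), function(g)
        matrix(cf$a[, g][cf$M], n, n))
    }
  } else {
    tl <- build_event_timeline(tree, reg, if (spec$biogeo) biogeo else NULL)
    cache$timeline <- tl
    ab <- if (is.null(reg)) "A" else reg$alphabet
    if (fam == "DDlin") cache$ddlin <- dd_lin_structure(tl, interaction, alphabet = ab)
    if (fam == "MC") cache$mcs <- mc_structure(tl, interaction)
    last <- tl$intervals[[length(tl$intervals)]]
    cache$d_present <- vapply(ab, function(g) {
      d <- if (interaction == "within") last$d else rowSums(last$A)
      max(c(0, d[last$regime == g]))
    }, numeric(1))
  }
  two <- spec$n_regimes == 2
  T <- tree_height(tree)
  named <- function(x) stats::setNames(x, ab[seq_along(x)])

  # family plumbing: psi -> unit-scale covariance V1 and mean design X
  ones <- matrix(1, n, 1)
  V1fun <- switch(fam,
    BM = function(psi) {
      if (!two) return(Reduce(`+`, cache$Tg))
      cache$Tg[[1]] + exp(psi[1]) * cache$Tg[[2]]
    },
    OU = function(psi) {
      alpha <- exp(psi[1])
      tm <- matrix(cache$closed$depths[cache$closed$M], n, n)
      exp(-2 * alpha * (T - tm)) * (1 - exp(-2 * alpha * tm)) / (2 * alpha)
    },
    EB = function(psi) {
      tip_moments_closed_form("EB", list(z0 = 0, sigma2 = 1, r = named(psi)),
                              tree, reg, cache = cache$closed)$V
    },
    DDexp = function(psi) {
      tip_moments_ode("DDexp", list(z0 = 0, sigma2 = 1, r = named(psi)),
                      cache$timeline, interaction = interaction)$V
    },
    DDlin = function(psi) {
      st <- cache$ddlin
      if (any(1 + psi * st$dmax[seq_along(psi)] < 0)) return(NULL)
      V1 <- st$Tm
      for (g in seq_along(psi)) V1 <- V1 + psi[g] * st$H[[g]]
      V1
    },
    MC = function(psi) {
      S <- if (op$allow_attraction) psi else -exp(psi)
      mc_cov(cache$mcs, named(S), 1, rk_h = op$rk_h)
    })
  Xfun <- if (fam == "OU" && two) {
    function(psi) ou_mean_design(cache$closed, exp(psi[1]))
  } else function(psi) ones

  npsi <- switch(fam, BM = if (two) 1L else 0L, OU = 1L,
                 EB = if (two) 2L else 1L, DDexp = if (two) 2L else 1L,
                 DDlin = if (two) 2L else 1L, MC = if (two) 2L else 1L)
  bounds <- switch(fam,
    BM = c(-12, 12),                     # log sigma-ratio
    OU = log(c(1e-4, 300) / T),          # log alpha
    EB = c(-40, 20) / T,                 # r per Myr
    DDexp = c(-40, 20) / max(n, 2),      # r per lineage
    DDlin = NULL,                        # set from admissibility below
    MC = if (op$allow_attraction) c(-300 / T, 300 / T) else log(c(1e-6, 300) / T))
  if (fam == "DDlin") {
    dmax <- max(cache$ddlin$dmax, 1)
    bounds <- c(-1 / dmax + 1e-10, 100 / dmax)
  }

  # negative profile log-likelihood over the reduced parameter vector
  neglog <- function(par) {
    psi <- par[seq_len(npsi)]
    if (npsi > 0 && (any(!is.finite(psi)) ||
                     any(psi < bounds[1] - 1e-9) || any(psi > bounds[2] + 1e-9)))
      return(1e10)
    V1 <- tryCatch(V1fun(psi), error = function(e) NULL)
    if (is.null(V1) || !all(is.finite(V1))) return(1e10)
    X <- Xfun(psi)
    if (profiled_scale) {
      ch <- tryCatch(chol(V1), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Xi <- backsolve(ch, X, transpose = TRUE)
      yi <- backsolve(ch, y, transpose = TRUE)
      beta <- tryCatch(solve(crossprod(Xi), crossprod(Xi, yi)),
                       error = function(e) NULL)
      if (is.null(beta)) return(1e10)
      q <- sum((yi - Xi %*% beta)^2)
      if (q <= 0) return(1e10)
      0.5 * (n * log(2 * pi) + n * log(q / n) + n) + sum(log(diag(ch)))
    } else {
      s <- exp(par[npsi + 1L])
      e2 <- err + if (estimate_err) exp(par[length(par)]) else 0
      Sig <- s * V1 + diag(e2, n)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Xi <- backsolve(ch, X, transpose = TRUE)
      yi <- backsolve(ch, y, transpose = TRUE)
      beta <- tryCatch(solve(crossprod(Xi), crossprod(Xi, yi)),
                       error = function(e) NULL)
      if (is.null(beta)) return(1e10)
      0.5 * (n * log(2 * pi) + sum((yi - Xi %*% beta)^2)) + sum(log(diag(ch)))
    }
  }

  # starting values (BM-moment-matched scale; slopes start flat)
  psi0 <- switch(fam, BM = 0, OU = log(1 / T), EB = rep(0, npsi),
                 DDexp = rep(0, npsi), DDlin = rep(0, npsi),
                 MC = if (op$allow_attraction) rep(-1 / T, npsi) else rep(log(1 / T), npsi))
  if (npsi == 0L) psi0 <- numeric(0)
  extra0 <- numeric(0)
  if (!profiled_scale) {
    vy <- stats::var(y)
    s0 <- log(max(vy / max(T, 1), 1e-12))
    extra0 <- s0
    if (estimate_err) extra0 <- c(extra0, log(max(0.05 * vy, 1e-12)))
  }

  base <- c(psi0, extra0)
  if (length(base) == 0L) {
    res <- list(par = numeric(0), value = neglog(numeric(0)), convergence = 0L)
  } else if (length(base) == 1L) {
    iv <- if (npsi == 1L) bounds else base + c(-15, 15)
    res <- opt1d(neglog, iv[1], iv[2])
  } else {
    set_seed_if(op$seed)
    starts <- list(base)
    if (op$n_starts > 1) starts <- c(starts, list(base + 0.7, base - 0.7))
    while (length(starts) < op$n_starts) {
      starts <- c(starts, list(base + stats::rnorm(length(base), 0, 1)))
    }
    starts <- starts[seq_len(min(length(starts), op$n_starts))]
    res <- optnd(neglog, starts)
  }
  if (res$value >= 1e10) stop_("all optimizer starts failed; likelihood could not be evaluated")

  # reassemble the full MLE parameter set
  psi <- res$par[seq_len(npsi)]
  V1 <- V1fun(psi)
  X <- Xfun(psi)
  if (profiled_scale) {
    ch <- chol(V1)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    beta <- as.numeric(solve(crossprod(Xi), crossprod(Xi, yi)))
    s_hat <- sum((yi - Xi %*% beta)^2) / n
    serr_hat <- 0
  } else {
    s_hat <- exp(res$par[npsi + 1L])
    serr_hat <- if (estimate_err) exp(res$par[length(res$par)]) else 0
    Sig <- s_hat * V1 + diag(err + serr_hat, n)
    ch <- chol(Sig)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    beta <- as.numeric(solve(crossprod(Xi), crossprod(Xi, yi)))
  }
  params <- assemble_params(fam, two, ab, psi, s_hat, beta, serr_hat,
                            allow_attraction = op$allow_attraction,
                            root_g = if (fam == "OU") {
                              if (!is.null(cache$closed)) cache$closed$root_g else 1L
                            } else NULL)
  if (estimate_err) params$sigma2_err <- serr_hat
  ll <- -res$value
  structure(list(model = model_name(spec), spec = spec, params = params,
                 logLik = ll, k = spec$k, n = n, AICc = aicc(ll, spec$k, n),
                 convergence = res$convergence == 0L,
                 info = list(T = T, d_present = cache$d_present %||% NULL,
                             profiled_scale = profiled_scale,
                             interaction = interaction, seed = op$seed)),
            class = "fit_result")
}

assemble_params <- function(fam, two, ab, psi, s, beta, serr,
                            allow_attraction = FALSE, root_g = NULL) {
  nm2 <- function(x) stats::setNames(x, ab[seq_along(x)])
  if (fam == "BM") {
    sig <- if (two) nm2(c(s, s * exp(psi[1]))) else s
    model_params(z0 = beta[1], sigma2 = sig)
  } else if (fam == "OU") {
    alpha <- exp(psi[1])
    theta <- if (two) nm2(beta) else beta[1]
    z0 <- if (two) unname(theta[root_g]) else beta[1]
    model_params(z0 = z0, sigma2 = s, alpha = alpha, theta = theta)
  } else if (fam == "EB" || fam == "DDexp") {
    model_params(z0 = beta[1], sigma2 = s,
                 r = if (two) nm2(psi) else unname(psi))
  } else if (fam == "DDlin") {
    model_params(z0 = beta[1], sigma2 = s,
                 b = if (two) nm2(s * psi) else unname(s * psi))
  } else {
    S <- if (allow_attraction) psi else -exp(psi)
    model_params(z0 = beta[1], sigma2 = s, S = if (two) nm2(S) else unname(S))
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.4f, k = %d, n = %d, AICc = %.4f%s\n",
              x$model, x$logLik, x$k, x$n, x$AICc,
              if (!x$convergence) " (NOT converged)" else ""))
  p <- x$params
  for (nm in names(p)) {
    cat(sprintf("  %s = %s\n", nm,
                paste(sprintf("%.6g", unname(p[[nm]])), collapse = " / ")))
  }
  invisible(x)
}

#' Fit and compare a set of models on one dataset
#'
#' @param specs List of [model_spec()] objects.
#' @inheritParams fit_model
#' @return A `model_comparison` data frame with columns `model`, `logLik`,
#'   `k`, `n`, `AICc`, `weight`, `convergence`, plus attributes `fits`
#'   (the full [fit_model()] results) and `best` (the [select_best()]
#'   verdict).
#' @export
compare_models <- function(specs, tree, regimes = NULL, biogeo = NULL, traits,
                           interaction = "within", options = list()) {
  fits <- lapply(specs, function(sp)
    fit_model(sp, tree, regimes, biogeo, traits, interaction, options))
  tbl <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    convergence = vapply(fits, `[[`, logical(1), "convergence"),
    stringsAsFactors = FALSE)
  tbl$weight <- akaike_weights(tbl$AICc)
  attr(tbl, "fits") <- stats::setNames(fits, tbl$model)
  attr(tbl, "best") <- select_best(tbl)
  class(tbl) <- c("model_comparison", "data.frame")
  tbl
}

#' Average model support over a stochastic-map bank
#'
#' Model support and parameter estimates are reported as arithmetic means
#' across fits conducted on each stochastic map; the modal best-fit model
#' across maps is recorded as the verdict.
#'
#' @param comparisons List of [compare_models()] results, one per map,
#'   with identical model sets.
#' @return A list with `table` (model, mean AICc, mean weight), `best`
#'   (modal best-fit), `best_per_map`, and `params` (per-model mean
#'   parameter vectors).
#' @export
aggregate_over_maps <- function(comparisons) {
  if (!length(comparisons)) stop_("need at least one map")
  models <- comparisons[[1]]$model
  for (cmp in comparisons) {
    if (!identical(sort(cmp$model), sort(models))) {
      stop_("inconsistent model sets across maps")
    }
  }
  W <- sapply(comparisons, function(cmp) cmp$weight[match(models, cmp$model)])
  A <- sapply(comparisons, function(cmp) cmp$AICc[match(models, cmp$model)])
  W <- matrix(W, nrow = length(models)); A <- matrix(A, nrow = length(models))
  best_each <- vapply(comparisons, function(cmp) attr(cmp, "best"), character(1))
  tab <- table(best_each)
  params <- lapply(models, function(mn) {
    ps <- lapply(comparisons, function(cmp) attr(cmp, "fits")[[mn]]$params)
    flat <- lapply(ps, function(p) unlist(p))
    Reduce(`+`, flat) / length(flat)
  })
  list(table = data.frame(model = models, AICc = rowMeans(A),
                          weight = rowMeans(W), stringsAsFactors = FALSE),
       best = names(tab)[which.max(tab)],
       best_per_map = best_each,
       params = stats::setNames(params, models))
}

# ---- derived metrics ------------------------------------------------------

#' Relative support for models with competition
#'
#' `max(MC, DD_lin, DD_exp weights) / (max(BM, OU, EB weights) +
#' max(MC, DD_lin, DD_exp weights))`; 0.5 under even support.
#'
#' @param weights Named vector of Akaike weights for the six single-regime
#'   models (names starting `BM`, `OU`, `EB`, `DDexp`, `DDlin`, `MC`).
#' @return Support index in `[0, 1]`.
#' @export
competition_support_index <- function(weights) {
  pick <- function(fams) {
    idx <- grep(paste0("^(", paste(fams, collapse = "|"), ")"), names(weights))
    if (!length(idx)) stop_("missing model in weight set")
    max(weights[idx])
  }
  wc <- pick(c("MC", "DDlin", "DDexp"))
  wn <- pick(c("BM", "OU", "EB"))
  wc / (wn + wc)
}

#' Relative support for two-regime models
#'
#' `max(two-regime weights) / (max(two-regime) + max(single-regime))`,
#' shifted by -0.5 so positive values favor regime structure.
#'
#' @param weights Named Akaike weights over the twelve models, two-regime
#'   entries suffixed `"_two"`.
#' @return Centered support index in `[-0.5, 0.5]`.
#' @export
two_regime_support_index <- function(weights) {
  is2 <- grepl("_two$", names(weights))
  if (!any(is2) || all(is2)) stop_("need both single- and two-regime weights")
  w2 <- max(weights[is2]); w1 <- max(weights[!is2])
  w2 / (w1 + w2) - 0.5
}

#' Log ratio of absolute regime-specific parameter estimates
#'
#' `ln(|par_first| / |par_second|)`; by convention the first element is the
#' tropical regime, so positive values mean a larger tropical magnitude.
#'
#' @param par Named numeric vector of length 2 (regime-specific estimates).
#' @param first,second Regime names (defaults `"tropical"`, `"temperate"`).
#' @return The log ratio.
#' @export
ln_abs_ratio <- function(par, first = "tropical", second = "temperate") {
  if (!all(c(first, second) %in% names(par))) {
    stop_("parameter vector lacks the requested regimes")
  }
  log(abs(par[[first]]) / abs(par[[second]]))
}

#' Evolutionary rate at the present
#'
#' BM: `sigma2`; EB: `sigma0^2 * exp(r*T)`; DD_exp:
#' `sigma0^2 * exp(r*N)`; DD_lin: `sigma0^2 + b*N`; OU and MC have no
#' time-varying rate and return `sigma2`. `N` is the number of lineages in
#' the fitted regime's sympatric pool at the present: the total tip count
#' without biogeography, the maximum per-continent sympatric count with.
#'
#' @param fit A [fit_result][fit_model()].
#' @return Named rate(s) at the present (one per regime for two-regime
#'   fits).
#' @export
rate_at_present <- function(fit) {
  p <- fit$params
  fam <- fit$spec$family
  T <- fit$info$T
  if (fam %in% c("BM", "OU", "MC")) return(p$sigma2)
  if (fam == "EB") return(p$sigma2 * exp(p$r * T))
  N <- fit$info$d_present
  if (is.null(N)) N <- fit$n
  if (length(p[[if (fam == "DDexp") "r" else "b"]]) > 1 && length(N) > 1) {
    N <- N[names(p[[if (fam == "DDexp") "r" else "b"]])]
  } else N <- max(N)
  if (fam == "DDexp") p$sigma2 * exp(p$r * N) else p$sigma2 + p$b * N
}

#' Total observational error of a fit
#'
#' Sum of the estimated nuisance error variance and the clade-level mean
#' squared standard error.
#'
#' @param fit A [fit_result][fit_model()].
#' @param traits The [trait_data()] the model was fit to.
#' @return Total error variance (units^2).
#' @export
total_error <- function(fit, traits) {
  (fit$params$sigma2_err %||% 0) + mean(traits$se2)
}
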