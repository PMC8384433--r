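# Model specifications and the observational-error multivariate-normal
# log-likelihood shared by all twelve models (six families x single/two
# regimes).

FAMILIES <- c("BM", "OU", "EB", "DDexp", "DDlin", "MC")

# Free-parameter counts before an estimated nuisance error variance:
#   single: BM 2 (z0, sigma2), OU 3 (+alpha), EB 3 (+r),
#           DDexp 3 (+r), DDlin 3 (+b), MC 3 (+S)
#   two:    one extra regime-specific copy of the "other" parameter
#           (BM: second sigma2; OU: two optima replacing z0).
k_table <- function(family, n_regimes) {
  base <- c(BM = 2, OU = 3, EB = 3, DDexp = 3, DDlin = 3, MC = 3)
  unname(base[family]) + (n_regimes == 2)
}

#' Define a model specification
#'
#' @param family One of `"BM"`, `"OU"`, `"EB"`, `"DDexp"`, `"DDlin"`,
#'   `"MC"`.
#' @param n_regimes 1 (single-regime) or 2 (regime-specific parameters).
#' @param biogeo Logical: restrict interactions/diversity to sympatric
#'   lineages using a biogeographic history? (Only meaningful for DD/MC.)
#' @param error `"none"` (use the trait table's `se2` only) or
#'   `"estimate"` (additionally estimate a shared nuisance error variance,
#'   adding one free parameter).
#' @return Object of class `model_spec` with the free-parameter count `k`.
#' @export
model_spec <- function(family = FAMILIES, n_regimes = 1, biogeo = FALSE,
                       error = c("none", "estimate")) {
  family <- match.arg(family)
  error <- match.arg(error)
  if (!n_regimes %in% c(1, 2)) stop_("n_regimes must be 1 or 2")
  k <- k_table(family, n_regimes) + (error == "estimate")
  structure(list(family = family, n_regimes = n_regimes, biogeo = biogeo,
                 error = error, k = k),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s (%s-regime%s%s), k = %d\n", x$family,
              if (x$n_regimes == 2) "two" else "single",
              if (x$biogeo) ", biogeography-aware" else "",
              if (x$error == "estimate") ", +error" else "", x$k))
  invisible(x)
}

model_name <- function(spec) {
  paste0(spec$family, if (spec$n_regimes == 2) "_two" else "_single")
}

#' Assemble a model parameter list
#'
#' Two-regime parameters are named numeric vectors over the regime
#' alphabet (e.g. `sigma2 = c(tropical = 0.2, temperate = 0.05)`).
#' Units: `z0` and optima in trait units; `sigma2` in units^2/Myr;
#' `alpha` and `S` in 1/Myr; EB slope `r` in 1/Myr; DD_exp slope `r` in
#' 1/lineage; DD_lin slope `b` in units^2/Myr per lineage; `sigma2_err`
#' in units^2.
#'
#' @param z0 Root state.
#' @param sigma2 Rate parameter (at the root for EB/DD).
#' @param r Slope (EB: per Myr; DD_exp: per lineage).
#' @param b DD_lin slope.
#' @param S MC coefficient; repulsion corresponds to `S < 0`.
#' @param alpha OU pull strength (`>= 0`).
#' @param theta OU optimum / optima.
#' @param sigma2_err Nuisance observational error variance (`>= 0`).
#' @return A plain list with the non-`NULL` entries.
#' @export
model_params <- function(z0 = NULL, sigma2 = NULL, r = NULL, b = NULL,
                         S = NULL, alpha = NULL, theta = NULL,
                         sigma2_err = NULL) {
  p <- list(z0 = z0, sigma2 = sigma2, r = r, b = b, S = S, alpha = alpha,
            theta = theta, sigma2_err = sigma2_err)
  p[!vapply(p, is.null, logical(1))]
}

#' Tip moments under any of the twelve models
#'
#' Dispatches to the closed forms (BM/OU/EB) or the timeline propagation
#' (DD/MC).
#'
#' @inheritParams log_likelihood
#' @return List with tip means `m` and covariance `V`.
#' @export
tip_moments <- function(spec, params, tree, regimes = NULL, biogeo = NULL,
                        interaction = "within", cache = NULL) {
  fam <- spec$family
  reg <- if (spec$n_regimes == 2) regimes else NULL
  if (fam %in% c("BM", "OU", "EB")) {
    tip_moments_closed_form(fam, params, tree, reg,
                            cache = cache$closed %||% NULL)
  } else {
    tl <- cache$timeline %||%
      build_event_timeline(tree, reg, if (spec$biogeo) biogeo else NULL)
    tip_moments_ode(fam, params, tl, interaction = interaction)
  }
}

# Gaussian log-density with a Cholesky factorization; `Sigma` must be the
# full tip covariance including observational error.
mvn_loglik <- function(y, m, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch) || any(!is.finite(diag(ch))) ||
      min(diag(ch)) <= 1e-7 * max(diag(ch))) {
    stop_("tip covariance is singular after error inflation; check for a parameter pathology or add jitter/observational error")
  }
  z <- backsolve(ch, y - m, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Log-likelihood of a trait table under a model
#'
#' The observed species means are modeled as multivariate normal with the
#' model's tip moments inflated by observational error:
#' `y ~ N(m, V + diag(se2_i + sigma2_err))`. The value is invariant to the
#' ordering of species rows.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()] list (with `sigma2_err` if the spec
#'   estimates error; defaults to 0).
#' @param tree Validated `phylo`.
#' @param regimes Optional [regime_history()] (required for two-regime
#'   specs).
#' @param biogeo Optional [biogeo_history()] (used when `spec$biogeo`).
#' @param traits A [trait_data()] table covering every tip.
#' @param interaction See [tip_moments_ode()].
#' @param cache Internal: precomputed structures reused during fitting.
#' @return The log-density (a scalar).
#' @export
log_likelihood <- function(spec, params, tree, regimes = NULL, biogeo = NULL,
                           traits, interaction = "within", cache = NULL) {
  if (spec$n_regimes == 2 && is.null(regimes)) {
    stop_("two-regime models require a regime history")
  }
  tr <- align_traits(traits, tree)
  mo <- tip_moments(spec, params, tree, regimes, biogeo,
                    interaction = interaction, cache = cache)
  err <- tr$se2 + (params$sigma2_err %||% 0)
  if (any(err < 0)) stop_("negative observational error variance")
  mvn_loglik(tr$mean, mo$m, mo$V + diag(err, nrow(tr)))
}
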