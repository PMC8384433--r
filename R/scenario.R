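# One-stop synthetic scenario generation: trees, regime histories (3-state
# Mk collapsed to the tropical/temperate contrast), biogeographic
# occupancy, stochastic-map banks, simulated traits and observational
# error, all reproducible from a single seed. Templates mirror clade shapes
# typical of continental bird families (tip counts and tropical/temperate
# splits such as 50 tips with 38 tropical, 122 with 89, 190 with 86).

#' Define a synthetic scenario
#'
#' @param n_tips Number of extant species.
#' @param n_tropical Target number of exclusively tropical tips (regimes
#'   are resimulated until the realized count is within `tol_frac` of the
#'   target; bounded retries).
#' @param model,params Generating trait model family and parameters (see
#'   [simulate_traits()]).
#' @param age Root age in Myr (default 40, a typical continental-family
#'   crown age).
#' @param birth,death Birth-death rates for the tree (per Myr); scenarios
#'   default to pure-birth trees, the standard choice for recovery studies.
#' @param K Number of biogeographic areas (0 = no biogeography / full
#'   sympatry).
#' @param gain,loss Area gain/loss rates for the occupancy history.
#' @param mk_rate Baseline Mk transition rate among
#'   tropical/temperate/both (per Myr).
#' @param map_bank Size of the stochastic-map bank sampled around the true
#'   history (0 = none; the study design calls for at least 20).
#' @param se2,sigma2_err Observational error injected into the simulated
#'   species means.
#' @param downsample Optional `c(p_tropical, p_temperate)` retained
#'   sympatry fractions applied to the biogeographic history before trait
#'   simulation (the fitted history stays unthinned, mirroring the
#'   continental-sympatry assumption).
#' @param tol_frac Tolerance on the tropical count as a fraction of the
#'   target (default 0.1).
#' @param dt Euler step for trait simulation (default T/1000).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_tips, n_tropical, model, params, age = 40,
                          birth = 0.15, death = 0, K = 0,
                          gain = 0.02, loss = 0.02, mk_rate = 0.02,
                          map_bank = 0, se2 = 0, sigma2_err = 0,
                          downsample = NULL, tol_frac = 0.1, dt = NULL) {
  if (n_tropical < 0 || n_tropical > n_tips) stop_("invalid tropical target")
  structure(as.list(environment()), class = "scenario_spec")
}

#' Scenario templates shaped like reference clades
#'
#' `"cracidae"`: 50 tips, 38 tropical; `"nectariniidae"`: 122 tips, 89
#' tropical; `"picidae"`: 190 tips, 86 tropical.
#'
#' @param template Template name.
#' @param model,params Generating model (default two-regime MC with
#'   repulsion stronger in the tropics).
#' @param ... Overrides passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
scenario_template <- function(template = c("cracidae", "nectariniidae", "picidae"),
                              model = "MC",
                              params = model_params(
                                z0 = 0, sigma2 = 0.05,
                                S = c(tropical = -0.08, temperate = -0.04)),
                              ...) {
  template <- match.arg(template)
  shape <- switch(template,
    cracidae = c(50, 38), nectariniidae = c(122, 89), picidae = c(190, 86))
  scenario_spec(n_tips = shape[1], n_tropical = shape[2], model = model,
                params = params, ...)
}

#' Generate a scenario: tree, histories, map bank and traits
#'
#' All randomness flows from `seed` through named substreams (tree,
#' regimes, biogeography, traits, error, map bank), so identical
#' `(spec, seed)` pairs give identical artifacts.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed.
#' @return List with `tree`, `regimes` (collapsed 2-state
#'   [regime_history()]), `regimes3` (pre-collapse 3-state history),
#'   `regime_bank` (collapsed stochastic maps, when `map_bank > 0`),
#'   `biogeo` (when `K > 0`), `biogeo_sim` (the possibly downsampled
#'   history actually used to simulate), `traits_true`, `traits`, `spec`,
#'   `seed`.
#' @export
make_scenario <- function(spec, seed) {
  sp <- spec
  tree <- simulate_bd_tree(sp$n_tips, sp$birth, sp$death,
                           seed = derive_seed(seed, 1), age = sp$age)
  states3 <- c("tropical", "temperate", "both")
  # transitions out of "tropical" made rarer/commoner to steer the split
  target <- sp$n_tropical / sp$n_tips
  f <- max(min(target, 0.95), 0.05)
  rates <- sp$mk_rate * c(
    (1 - f), (1 - f),   # tropical -> temperate, tropical -> both
    f, f,               # temperate -> tropical, temperate -> both
    f, (1 - f)) * 2     # both -> tropical, both -> temperate
  Q <- mk_generator(rates, states3)
  root3 <- if (target >= 0.5) "tropical" else "temperate"
  tol <- max(1, sp$tol_frac * sp$n_tropical)
  reg3 <- NULL
  for (try in 1:200) {
    cand <- simulate_regime_history(tree, Q, seed = derive_seed(seed, 100 + try),
                                    root_state = root3)
    n_trop <- sum(collapse_state(tip_states(cand)) == "tropical")
    if (abs(n_trop - sp$n_tropical) <= tol) { reg3 <- cand; break }
  }
  if (is.null(reg3)) stop_("could not satisfy the tropical/temperate split after 200 retries")
  regimes <- collapse_regimes(reg3)
  biogeo <- NULL
  if (sp$K > 0) {
    biogeo <- simulate_biogeo_history(tree, sp$K, sp$gain, sp$loss,
                                      seed = derive_seed(seed, 2),
                                      root_occupancy = rep(1, sp$K))
  }
  biogeo_sim <- biogeo
  if (!is.null(sp$downsample)) {
    if (is.null(biogeo)) stop_("downsampling requires K > 0 areas")
    biogeo_sim <- downsample_sympatry(biogeo, tip_states(regimes),
                                      p_tropical = sp$downsample[1],
                                      p_temperate = sp$downsample[2],
                                      seed = derive_seed(seed, 3))
  }
  traits_true <- simulate_traits(tree, sp$model, sp$params, regimes,
                                 biogeo_sim, dt = sp$dt,
                                 seed = derive_seed(seed, 4))
  traits <- if (any(sp$se2 > 0) || sp$sigma2_err > 0) {
    add_observational_error(traits_true, sp$se2, sp$sigma2_err,
                            seed = derive_seed(seed, 5))
  } else traits_true
  regime_bank <- NULL
  if (sp$map_bank > 0) {
    bank3 <- sample_stochastic_maps(tree, Q, tip_states(reg3),
                                    n = sp$map_bank,
                                    seed = derive_seed(seed, 6))
    regime_bank <- lapply(bank3, collapse_regimes)
  }
  list(tree = tree, regimes = regimes, regimes3 = reg3,
       regime_bank = regime_bank, biogeo = biogeo, biogeo_sim = biogeo_sim,
       traits_true = traits_true, traits = traits, spec = sp, seed = seed)
}
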