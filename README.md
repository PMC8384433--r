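# compevol

Phylogenetic comparative methods ask whether the tempo (rate) and mode
(generating process) of continuous trait evolution differ between groups of
lineages — for example between tropical and temperate breeders, where the
biotic-interactions hypothesis predicts stronger competition at low
latitudes. Testing that prediction requires models in which competition
between co-occurring lineages shapes trait evolution, with parameters that
may differ between two lineage *regimes*, while accounting for
biogeographic overlap and for the error with which species means are
measured. `compevol` implements that toolkit: simulation, exact
moment-based likelihoods, maximum-likelihood fitting and AICc model
selection for six model families in single- and two-regime form, plus the
discrete-character machinery (Mk fitting and stochastic character mapping)
needed to build regime histories, and fully seeded harnesses for
recovery and power studies.

## Models

With `X_t(j)` the trait of lineage `j` at time `t` since the root, `g(j,t)`
its regime, and `A(t)` the 0/1 sympatry matrix derived from biogeographic
occupancy (unit diagonal; all ones when biogeography is ignored), the
families are:

| family | SDE / rate | regime-specific parameters |
|---|---|---|
| BM | `dX = sigma dW` | `sigma2_trop, sigma2_temp` |
| OU | `dX = alpha (theta - X) dt + sigma dW` | optima `theta_trop, theta_temp` |
| EB | rate `sigma0^2 exp(r t)` | slopes `r_trop, r_temp` (per Myr) |
| DD_exp | rate `sigma0^2 exp(r d_j(t))` | slopes per lineage |
| DD_lin | rate `sigma0^2 + b d_j(t)` (must stay >= 0) | slopes per lineage |
| MC | `dX = S (x_bar_j - X) dt + sigma dW` | `S_trop, S_temp` (`S < 0` = repulsion) |

Here `d_j(t) = sum_l A_jl(t)` counts the sympatric same-regime lineages
(self included) and `x_bar_j` is the sympatry-weighted mean trait of the
same-regime pool, so matching competition (MC) repels lineages from the
local phenotypic mean (character displacement) while diversity-dependent
(DD) rates track ecological opportunity. Observed species means add
observational error: `y_i ~ N(m_i, V_ii + SE_i^2 + sigma2_err)`, where
`SE_i^2` is the known sampling variance of the species mean and
`sigma2_err` an optionally estimated nuisance variance.

Likelihoods are multivariate normal on the joint tip distribution: closed
forms for BM/OU/EB, and covariance propagation along an event timeline
(branchings, regime switches, occupancy changes) for DD/MC, with an exact
block-projector update under complete within-regime sympatry and classical
Runge-Kutta otherwise. Model selection uses AICc with the simpler-model
rule (a model with fewer parameters within 2 AICc units supersedes the
minimum), Akaike weights, and averaging over banks of stochastic maps.

## Worked example

Simulate a 60-species clade in which tropical lineages repel each other
about twice as strongly as temperate ones, then ask whether the data
prefer plain Brownian motion, matching competition, or latitude-specific
competition:

```r
library(compevol)

sc <- make_scenario(
  scenario_spec(60, 36, "MC",
    model_params(z0 = 0, sigma2 = 0.05,
                 S = c(tropical = -0.08, temperate = -0.04))),
  seed = 42)

specs <- list(model_spec("BM"), model_spec("MC"), model_spec("MC", 2))
cmp <- compare_models(specs, sc$tree, sc$regimes, traits = sc$traits,
                      options = list(seed = 1))
cmp
#>       model  logLik k  AICc    weight
#> 1 BM_single -101.18 2 206.6 1.609e-05
#> 2 MC_single  -92.24 3 190.9 4.064e-02
#> 3    MC_two  -87.93 4 184.6 9.593e-01
attr(cmp, "best")
#> [1] "MC_two"

fit <- attr(cmp, "fits")$MC_two
fit
#> MC_two fit: logLik = -87.9300, k = 4, n = 60, AICc = 184.5873
#>   z0 = -0.243215
#>   sigma2 = 0.0442701
#>   S = -0.0773649 / -0.0258275
ln_abs_ratio(fit$params$S)
#> [1] 1.097
```

The two-regime MC model wins decisively (Akaike weight 0.96), the
repulsion estimates `S = (-0.077, -0.026)` bracket the generating values
`(-0.08, -0.04)`, and the log magnitude ratio `ln(|S_trop|/|S_temp|) =
1.1 > 0` correctly signals stronger competition in the tropics.

Real analyses start from files instead of a generator: `parse_newick()`
reads the chronogram, `parse_simmap()` reads stochastic maps of regimes or
occupancy (phytools curly-brace dialect, root-ward segment first),
`read_trait_data()` reads `species, mean, n, se2` tables, and fitting over
a bank of maps is `compare_models()` per map followed by
`aggregate_over_maps()`.

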