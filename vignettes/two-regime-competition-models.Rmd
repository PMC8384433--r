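---
title: "Two-regime models of trait evolution with competition and biogeography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-regime models of trait evolution with competition and biogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compevol)
```

## The models and their assumptions

`compevol` models a single continuous trait evolving along a rooted,
binary, ultrametric chronogram. Time runs from 0 at the root to the root
age `T` at the present, so a rate of the form `sigma0^2 * exp(r*t)` with
`r < 0` declines since the root. Six families are implemented, each in a
single-regime form (one parameter set for the whole clade) and a
two-regime form in which selected parameters differ between two mutually
exclusive lineage classes — in the motivating application, species
breeding exclusively in the tropics versus species whose breeding range
includes the temperate zone:

* **BM** — constant-rate diffusion; two-regime form has regime-specific
  rates `sigma2`.
* **OU** — diffusion with a pull `alpha` toward an optimum; the two-regime
  form shares `alpha` and `sigma2` and estimates two optima, with the root
  state fixed at the root-regime optimum (the parameterization follows the
  model table: the regime-specific entries are the optima).
* **EB** — rate an exponential function of time since the root,
  `sigma0^2 * exp(r_g * t)`; regime-specific slopes.
* **DD_exp / DD_lin** — rate an exponential or linear function of the
  number of coexisting lineages: `sigma0^2 * exp(r_g * d_j(t))` or
  `sigma0^2 + b_g * d_j(t)`, where `d_j(t)` counts the sympatric
  same-regime lineages including the focal one. The linear rate must stay
  non-negative; parameters that violate this are rejected as inadmissible
  rather than clamped, because the likelihood is undefined there.
* **MC** (matching competition) — a deterministic pull
  `S_g * (xbar_j - X_j)` toward (for `S > 0`) or away from (`S < 0`,
  repulsion/character displacement) the sympatry-weighted mean trait
  `xbar_j` of the same-regime pool, self included, plus constant-rate
  diffusion.

Assumptions shared by all: the trait is univariate and Gaussian given the
tree and histories; regimes and biogeography are piecewise-constant,
externally supplied histories (stochastic maps), not jointly estimated
with the trait process; interactions act instantaneously through current
sympatry; and branching copies the parent trait to both daughters.

Two structural conventions matter downstream. Self-sympatry is always 1,
so with every lineage in one area the biogeography-aware models reduce
exactly to their full-sympatry counterparts. And interactions are
restricted to *same-regime* sympatric lineages, exactly as the two-regime
equations are written; the alternative reading (all sympatric lineages
interact, the regime sets only the focal coefficient) is available via
`interaction = "across"`. The readings genuinely differ: a two-regime
DD or MC model with equal parameters in both regimes equals the
single-regime model only under `"across"`, because the same-regime
diversity count `n_t(A)` is not the total count. A suspected typo in the
printed two-regime DD_exp equations (the first regime's slope appearing
in both branches) is implemented as slope `r_B` in regime B, consistent
with the regime-free form.

## Observational error

Species means are estimated from finite samples and carry additional
non-heritable deviations (plasticity, instrument error). Both are lumped
into one "observational error" term: the likelihood of observed means `y`
is `N(m, V + diag(SE_i^2 + sigma2_err))`, with `SE_i^2` supplied per
species in the trait table and `sigma2_err` an optional shared nuisance
variance estimated by ML (adding one free parameter to `k`). Fitting
"excluding error" is the special case `SE_i^2 = 0`, `sigma2_err = 0`.

## Likelihood computation

BM, OU and EB have closed-form tip moments (path sums of per-segment rate
integrals; the standard fixed-root OU covariance). DD and MC moments are
propagated along an *event timeline*: between consecutive events
(branchings, regime switches, occupancy changes) the alive set, regimes
and sympatry matrix `A` are constant, and

    dm/dt = R m,    dV/dt = R V + V R' + D

with `R = 0` and diagonal `D` for DD (the update is then exact), and for
MC `R = diag(S_g) (W - I)` with `W` the row-normalized masked sympatry
matrix and `D = sigma2 * I`. `R` has zero row sums, so the mean stays at
the root state for every family handled this way. When every pair of
interacting lineages is sympatric, `W` is a block-averaging projector and
the interval update (matrix exponential plus noise integral) is evaluated
exactly in `O(n^2)`; otherwise classical Runge-Kutta is used with the
substep chosen so that `max|S| * h <= 0.02` (the `rk_h` control). The
integrator is cross-checked in the test suite against `deSolve::ode`
(rtol 1e-10), against a hand-derived two-lineage solution, and against
10,000-replicate Euler simulations. At branchings the parent's row and
column of `V` are duplicated. The likelihood is evaluated on the dense
tip covariance by Cholesky factorization — interaction models break the
independence structure that pruning algorithms exploit, and the slicing
rule (below) keeps `n` at most a few hundred.

## Fitting

`fit_model()` maximizes a reduced profile likelihood. The mean parameters
(`z0`, or the two OU optima through their linear design) are profiled by
GLS at every evaluation. When the data carry no observational error, the
overall rate scale is also profiled analytically: every family's
covariance is proportional to its rate parameter once DD_lin is
reparameterized by the slope-to-rate ratio `b/sigma2` (whose admissibility
bound depends only on the ratio). What remains is a 0-2 dimensional
search over slopes, `alpha`, or `S`: a bracketed grid-plus-golden-section
search in one dimension, Nelder-Mead with multiple starts (default 4: a
moment-matched base, +/- perturbations, and seeded random starts)
otherwise. Variances are optimized on the log scale; `alpha` and `|S|` on
the log scale with generous bounds relative to the tree height; by
default `S` is constrained to repulsion (`S <= 0`) via `S = -exp(psi)`,
with `allow_attraction` to lift the constraint. Reported magnitudes use
`|S|`. Preconditions follow the study design: at least 10 tips, and for
two-regime fits at least 10 tips in each regime.

Model selection: `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `n` the
number of tips with data; Akaike weights; and the simpler-model rule
applied iteratively among models within 2 AICc of the minimum (ties by
lower AICc, then fewer parameters, then name). Support for stochastic-map
banks is averaged arithmetically across per-map fits, with the modal
best-fit model as the verdict. Derived metrics follow the reference
formulas: the competition support index
`max(w_MC, w_DDlin, w_DDexp) / (max(w_BM, w_OU, w_EB) + max(w_MC, w_DDlin, w_DDexp))`,
the two-regime support index (centered at 0 by subtracting 0.5), the
contrast `ln(|par_trop|/|par_temp|)`, rates at the present
(`sigma0^2 e^{rT}`, `sigma0^2 e^{rN}`, `sigma0^2 + bN` with `N` the
present-day sympatric pool size — total tips without biogeography, the
largest per-continent pool with), and total error (nuisance MLE plus the
clade mean `SE^2`).

## Regimes, biogeography and sympatry inputs

Breeding-range bands classify as tropical/temperate/both against a closed
tropics interval of +/-23.437 degrees; a band touching the boundary
exactly counts as "both" (conservative, and measure-zero for continuous
data). A 3-state all-rates-different Mk model is fitted by Felsenstein
pruning + ML, stochastic maps are drawn by node-conditional (Bollback)
sampling with uniformized within-branch bridges, and the "both" category
is collapsed into "temperate" per segment, so "tropical" always means
exclusively tropical. Range overlap is scored by the Szymkiewicz-Simpson
coefficient `overlap / min(area1, area2)` with a 20% sympatry threshold
(inclusive). Clades larger than 200 tips are sliced by sliding a cut line
from the root in 0.1-Myr steps until every crossing clade is below 200
tips, keeping monophyletic subclades with at least 10 species.

Continental-scale occupancy overstates true sympatry, so
`downsample_sympatry()` thins it: in the default lineage-level reading,
for each area and regime a fraction `p` (rounded down) of the occupying
tips is retained in the area's interacting set, dropped tips lose the
area along their terminal branch, and a tip dropped everywhere moves to a
private singleton area — it then interacts with nobody, while internal
(ancestral) branches are untouched. The alternative pair-level reading
(thinning edges of a tip sympatry matrix, mixed-regime pairs at the mean
of the two rates) is available with `unit = "pair"`. The wording of the
source design admits both; the lineage reading is the default because
the downsampling is described as acting on taxa, not pairs.

## Synthetic scenarios and what they do (not) emulate

`make_scenario()` generates complete, reproducible test beds: a pure-birth
chronogram rescaled to a 40-Myr crown age (typical of continental bird
families; pure-birth is the standard choice in recovery studies — under
substantial extinction the few surviving deep nodes leave root-anchored
parameters essentially unidentified at these clade sizes), a 3-state Mk
regime history with baseline rate 0.02/Myr steered and resampled until
the tropical tip count hits its target within 10%, optional area
gain/loss biogeography (0.02/Myr per area), a stochastic-map bank
conditioned on the realized tip states, Euler-simulated traits
(`dt = T/1000` by default; `T/100` is the coarsest accepted), and
optional observational error. Templates mirror reference clade shapes
(50 tips / 38 tropical; 122 / 89; 190 / 86). All randomness flows from
one seed through named substreams, so a scenario is a pure function of
`(spec, seed)`.

The recovery and power studies in the test suite use 100-tip scenarios
with a 60/40 tropical/temperate split, 20 replicates, root state
`z0 = 5`, and generating values `sigma2 = (0.2, 0.05)` (BM),
`alpha = 0.1` with optima `(5, 8)` (OU), EB slopes `(-0.12, -0.06)`/Myr,
DD_exp slopes `(-0.04, -0.02)`/lineage, DD_lin slopes
`(-0.0015, -0.0008)`, and `S = (-0.08, -0.04)`/Myr; the
misspecified-sympatry power study uses `S = (-0.1, -0.02)` (a 5-fold
contrast) with half of each regime's within-continent taxa truly
sympatric. These magnitudes sit in the regime where maximum likelihood is
informative at `n = 100` (e.g. `|r| T` of 2.4-4.8 for EB); they were
chosen by a design-phase identifiability analysis and are not revisited.

What the generator does not emulate: real morphological trait
distributions (principal-component loadings, allometry), phylogenetic
uncertainty (the topology is fixed within a scenario), range geometry
(areas are abstract; overlaps enter as precomputed coefficients),
paleolatitude drift, and diversification that depends on the trait.
Passing tests therefore demonstrate internal correctness and statistical
behavior under the stated generating processes, not performance on any
empirical dataset.

## Numerical choices

* Ultrametricity tolerance `1e-6 * T` relative (published chronograms
  carry rounding noise); segment tiling tolerance `1e-6` relative to tree
  height; simultaneous timeline events merged within `1e-9 * T`.
* SIMMAP dialect: phytools curly braces, root-ward segment first, both in
  text and in stored segments; branch length is the sum of durations and
  is validated against a reference tree when one is supplied.
* `r -> 0`, `b -> 0`, `S -> 0` and `alpha -> 0` limits are taken
  analytically, never by division.
* MC integrator: exact block update when sympatry is complete within
  regimes; otherwise RK4 with `max|S| * h <= 0.02`, which agrees with a
  reference adaptive integrator to ~1e-6 on the tested fixtures.
* Optimizer: Nelder-Mead reltol 1e-8 (with a bracketed 1-D search where
  the profile leaves one parameter), bounds expressed in units of `1/T`
  or `1/n` so they scale with the problem.
* Selection-rule ties: lower AICc, then fewer parameters, then
  lexicographic model name (the rule's source does not specify ties).

## Known limitations

* The root rate `sigma0^2` of the EB family is weakly identified: it is
  an extrapolation to `t = 0` supported only by the earliest few
  lineages. The recovery suite shows its ML sampling distribution is
  log-skewed enough that the median over 20 replicates at `n = 100` sits
  well below the generating value even with data drawn exactly from the
  model; EB slope estimates, and all parameters of the other five
  families, recover well. Conclusions about EB root rates at these clade
  sizes should rest on rates at the present instead.
* Two-regime OU fixes the root state at the root-regime optimum; a
  stationary-root variant is not implemented.
* Single trait only; no within-branch rate heterogeneity beyond the
  regime/biogeography structure; no joint inference of histories and
  trait process; no Bayesian machinery.
* DD_lin's admissibility region couples the slope to the maximum
  sympatric diversity; fits near the boundary can pin at it, which the
  convergence flag does not distinguish from an interior optimum.
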