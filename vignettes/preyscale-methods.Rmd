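---
title: "Methods: phylogenetic analysis of predator-prey mass scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic analysis of predator-prey mass scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `preyscale`, the
conventions the package had to choose where more than one was defensible,
what the synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## Data model and transforms

The unit of analysis is a predator species with its taxonomy
(order/family/genus), foraging environment (aquatic or terrestrial), body
mass, and the minimum and maximum mass of prey it consumes, all in kg.
Analyses run on log10-transformed masses. Prey-mass **range** is defined on
the raw kg scale, `prey_max - prey_min`, and only then log10-transformed;
the alternative (difference of logs, i.e. a ratio) is rejected because
range is a mass, not a ratio. A species whose reported minimum and maximum
prey masses coincide has an undefined log range: it is kept for the
min/max analyses, excluded (with a warning, and pruning the tree to match)
from range analyses.

## PGLS with Pagel's lambda

For response $y$ ($n$ species), design matrix $X$ and phylogenetic
covariance $V$ (entry $V_{ij}$ = shared root-to-MRCA branch length on the
dated tree), the residual model is
$e \sim \mathcal N(0,\; \sigma^2 V(\lambda))$, where $V(\lambda)$
multiplies the off-diagonal entries of $V$ by $\lambda \in [0,1]$.
$\hat\beta = (X^\top V^{-1}X)^{-1} X^\top V^{-1} y$ and
$\hat\sigma^2_{ML} = e^\top V^{-1} e / n$ are computed from a single
Cholesky factorization per $\lambda$; the profiled log-likelihood is
$-\tfrac n2 \log(2\pi\hat\sigma^2_{ML}) - \tfrac12\log|V| - \tfrac n2$.
$\lambda$ is maximized over $[0,1]$ by bounded scalar optimization seeded
by an 11-point grid (local optima are rare but the grid guards against
them); both boundaries are admissible. ML rather than REML is used
throughout because AICc comparisons across models with different fixed
effects require ML.

**Standard errors.** Coefficient SEs use the df-adjusted residual variance
$e^\top V^{-1} e/(n-p)$ on the $(X^\top V^{-1}X)^{-1}$ diagonal — the
convention of the field's GLS implementations — rather than
$\hat\sigma^2_{ML}$. The package's own coverage calibration (500
replicates at $n=200$ in the acceptance suite) showed the ML-variance SEs
to produce slightly anti-conservative 95% intervals; the df-adjusted form
restores nominal coverage. Likelihood, $\hat\sigma^2$ and AICc are
unaffected.

**Parameter count.** AICc needs a definite $k$:
$k = p + 1\,(\sigma^2) + 1\,(\lambda\ \text{when ML-estimated})$. A
fixed-$\lambda$ fit counts $p + 1$. This is a declared convention —
treating $\lambda$ as a free parameter is the statistically defensible
choice since it is estimated from the same data.

**Effect size.** The reported effect size $r$ has, by default, the
likelihood-ratio form
$r = \sqrt{1 - \exp\{\tfrac2n(\ell_0 - \ell_m)\}}$ against the
intercept-only (null) fit on the same tree; a t-statistic alternative
$r = \sqrt{t^2/(t^2 + \mathrm{df})}$ (mass coefficient, df $= n-p$) is
available via `effect_r_method = "t"`. Both are conventions: no canonical
definition exists for PGLS, so the choice is exposed rather than hidden.

**Numerics.** Each $\lambda$ evaluation refactorizes $V(\lambda)$; a
Cholesky failure or a condition-number proxy (squared ratio of extreme
Cholesky diagonal entries) above $10^{12}$ aborts with a diagnostic. Rank
deficiency of $X$ is an error, not a silent drop.

## Model set and ensemble aggregation

Three nested models are fitted per tree: interaction
($1, x, z, xz$ with $x$ = log mass, $z$ = environment, aquatic = 0 /
terrestrial = 1), mass-only ($1, x$) and null ($1$). The null model's
$\lambda$ is estimated too, making it a genuine Brownian/lambda
intercept-only model. Under the 0/1 coding the aquatic regression line is
$(\beta_{mass}, \beta_0)$ and the terrestrial line
$(\beta_{mass}+\beta_{int}, \beta_0+\beta_{env})$, so $\beta_{int}$ is
directly the slope difference whose CI is the headline test.

Across an ensemble of resolved trees: ΔAICc is computed per tree against
that tree's best model (ties within $10^{-12}$ broken towards fewer
parameters), then summarized as the mean and the 2.5/97.5 percentiles over
trees. Coefficients are aggregated as mean estimate across trees with
CI = mean estimate ± 1.96 × mean SE; percentile aggregation of per-tree
estimates is available (`coef_ci = "percentile"`). Percentile-over-trees
for ΔAICc and the 1.96·SE rule for coefficients are declared conventions:
the aggregation behind published ensemble CIs of this kind is typically
unstated, and these are the natural readings. Single-tree fit failures are
excluded with a warning; more than 5% failing is an error.

## Polytomy resolution

Published dated supertrees contain soft polytomies. The resolver replaces
the Bayesian machinery used historically for this task (out of scope here)
with coalescent-style sequential random joins: within a polytomy of age
$t_p$, two current children are drawn uniformly at random and joined at an
age uniform on $(\max(a_i,a_j),\,t_p)$, repeating until binary. This
randomizes topology and node ages jointly, preserves the tip set,
ultrametricity and every pre-existing node age, and introduces no negative
branches. For a trichotomy with young children each of the three labeled
topologies arises with probability 1/3 (verified by simulation in the
acceptance suite). The uniform-age choice is a declaration, not an
inference: it is the maximum-entropy option consistent with the dating
constraints. Per-member seeds derive deterministically from the master
seed, so ensembles are bit-reproducible. Ultrametricity is enforced within
a relative tolerance of $10^{-6}$ × tree height (configurable), absorbing
the rounding error real supertree files carry.

A consequence of this design: ensemble variation reflects *only* the
unresolved parts of the input tree. Ages of resolved nodes are never
perturbed, so if the historical analysis also varied dated-node ages, this
package's ensemble CIs will be narrower on real data.

## Variance components

The taxonomic decomposition fits, by ML,
$y = \beta_1 x + \beta_2 z + u_{order} + u_{family} + u_{genus} + \varepsilon$
with nested random intercepts (lme4; labels are validated to nest:
each family within one order, each genus within one family). Random
components are the ML variance estimates. The two fixed covariates
contribute Nakagawa–Schielzeth-style components: the variance over species
of the term's fitted contribution ($\widehat\beta\,x$). The residual is
always computed; because presentations of such tables sometimes omit the
residual row, `renormalize = TRUE` re-expresses percentages over the five
named sources only. How a continuous covariate should yield a "variance
component" has no unique answer; this choice is documented and tested by
recovery (a world with only between-order variation puts ≥95% on order; a
pure mass-scaling world puts ≥95% on mass). Components from factors with a
single level are 0 with a warning. lme4 singular fits (a variance on the
boundary) are accepted — a zero component is a legitimate estimate.

## Distribution moments

Moments are computed on the log10 scale (the scale of all analyses;
whether historical summary tables used log or raw kg is not always stated
— log10 is the consistent choice). Skewness is the adjusted
Fisher–Pearson $G_1$; kurtosis is reported primarily as bias-adjusted
*excess* kurtosis (normal = 0), with the raw fourth standardized moment
also available, because verbal conventions for kurtosis are notoriously
inconsistent. The "mode" of a continuous mass variable is the modal
log10-decade bin ($[10^i, 10^{i+1})$ kg), with the full per-decade
histogram attached so multi-decade groupings can be formed; ties are
returned explicitly. Two raw-kg spreads are distinguished: `range_kg`
(spread of the response within a group) and `prey_span()`
(`max(prey_max) - min(prey_min)`, the group's full exploited prey
spectrum).

## The synthetic world

`sim_config()` defaults state one fixed world, used by all recovery tests:

- **Tree**: birth–death with birth 1, death 0.5 per lineage-time,
  conditioned on n = 108 tips, rescaled to unit root height (PGLS is
  invariant to time units; unit height makes σ² the residual variance
  accumulated root-to-tip). 15% of internal nodes are collapsed into soft
  polytomies, emulating supertree irresolution.
- **Traits**: log10 predator mass ~ N(1, 1.25²) — medians near 10 kg with
  realistic spread from stoat-sized to whale-sized; generative
  coefficients β₀ = −2.96, β_mass = −0.03 (aquatic slope ≈ 0),
  β_env = −0.34, β_int = 1.16 (terrestrial slope ≈ 1.13), λ = 0.62, all
  taken from the fitted minimum-prey world the package is designed to
  re-examine; σ² = 1 (residual SD of 1 log10 unit, a realistic scatter
  given total response variances near 3).
- **Environment**: a clade of roughly 57/108 of the tips is marked
  aquatic. Clade assignment is the default deliberately: aquatic
  carnivores are phylogenetically clustered in reality, and that
  confounding of environment with phylogeny is exactly what λ must absorb
  — random assignment (available via `env_assignment = "random"`) would
  make the test too easy.
- **Taxonomy**: order/family/genus labels are the lineages crossing
  0.75/0.5/0.25 of tree height, so taxonomic and phylogenetic structure
  agree as in real data.
- **Prey max**: `log_prey_max = log_prey_min + max(0.05, 0.5 + 0.15·x + N(0, 0.25²))`,
  keeping max > min always and letting niche breadth grow with mass.

What the generator does **not** emulate: measurement error and
literature-sourcing heterogeneity in prey records; categorical prey
reported as a single mass; trait-dependent diversification; age
uncertainty in resolved nodes. A green recovery test therefore establishes
that the estimators are correct and calibrated *under the assumed model*,
not that real data satisfy the model.

## Design choices on open points

- Species-name matching normalizes whitespace to underscores and is exact
  after that; mismatches error with the offending names listed.
- The acceptance target list is empty by construction: every printed
  number of the motivating study depends on a non-redistributable data
  appendix and an external supertree. The acceptance suite is therefore
  property- and simulation-based (GLS-vs-OLS, λ recovery with boundary
  behavior, 93–97% CI coverage, model-selection calibration at n = 108,
  resolver uniformity, variance-source recovery).
- Replicate counts in the acceptance suite (100/500/200) are the stated
  desk-scale design and complete in ~1.5 min total; seeds are fixed
  constants chosen before results were observed.

## Known limitations

- λ is the only covariance transform; no OU/kappa/delta, no measurement
  error model, no within-species variation.
- The ensemble varies only polytomy resolutions, not dated-node ages.
- The variance decomposition is taxonomic, not tree-based; order/family/
  genus are coarse proxies for phylogeny and the split between them and
  the residual depends on the mixed-model variance estimates, which can
  sit on the boundary (zero) in small samples.
- AICc's k and the effect-size r are conventions (above); comparisons with
  tables computed under other conventions are approximate.
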