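# preyscale

Carnivorous mammals — from weasels to baleen whales — differ enormously in
the sizes of prey they take, and close relatives tend to take similar prey
because they inherit morphology, foraging strategy and environment from
common ancestors. `preyscale` is an R package for asking how the **minimum,
maximum and range of prey body mass** scale with **predator body mass**
across such a clade, and whether that scaling differs between **aquatic and
terrestrial** foragers, while treating species as phylogenetically
non-independent observations.

## The model

For a response *y* (log10 minimum, maximum or range of prey mass, kg) the
package compares three nested models by PGLS:

- **interaction** — y = β₀ + β_mass·x + β_env·z + β_int·x·z
- **mass only** — y = β₀ + β_mass·x
- **null** — y = β₀ (Brownian intercept-only model)

where *x* is log10 predator mass and *z* codes environment (aquatic = 0,
terrestrial = 1, so β_int is the terrestrial-minus-aquatic slope
difference). Residuals are e ~ MVN(0, σ²·V(λ)): V holds the shared
branch lengths of each species pair on a dated tree, and Pagel's λ ∈ [0, 1]
rescales its off-diagonals — λ = 1 is pure Brownian phylogenetic signal,
λ = 0 phylogenetic independence. λ is estimated by maximum likelihood
(profile over [0, 1]); models are ranked by
AICc = −2lnL + 2k + 2k(k+1)/(n−k−1), with models within 2 ΔAICc considered
equally supported. Because dated supertrees contain soft polytomies, the
whole model set is run over an ensemble of stochastically resolved binary
trees and the support statistics are aggregated across the ensemble.

Two complementary views of the same data are included: a taxonomic
variance-components decomposition (nested random intercepts for
order/family/genus plus mass and environment fixed-effect components), and
descriptive moments of the prey-mass distributions (mean, median, SD,
skewness, excess kurtosis, modal log10-decade bin, raw-kg spans), overall
and per environment.

A synthetic-data generator (`simulate_dataset()`) draws birth–death trees
with soft polytomies and traits from exactly the λ-Brownian regression
model above, so every stage of the pipeline is validated by parameter
recovery in the test suite.

## Worked example

A 20-species synthetic dataset (generated by the package's own simulator;
see `inst/extdata/`) ships with the package:

```r
library(preyscale)
tab <- read_trait_table(system.file("extdata", "synthetic_traits_n20.csv", package = "preyscale"))
tr  <- read_newick(system.file("extdata", "synthetic_tree_n20.nwk", package = "preyscale"))
ens <- resolve_polytomies(prune_tree(tr, species_set(tab)), n_trees = 50, seed = 1)
run_model_set(tab, ens, response = "min")
```

```
PGLS model set, response 'min', 50 trees (0 failed)
       model delta_aicc_mean delta_aicc_ci_low delta_aicc_ci_high lambda_mean
        null          25.682            24.928             26.846       0.091
   mass_only          23.127            22.124             24.830       0.232
 interaction           0.000             0.000              0.000       0.488
 effect_r_mean equally_supported
            NA             FALSE
         0.499             FALSE
         0.916              TRUE
best model: interaction
environment lines (interaction model):
 environment  slope intercept
     aquatic -0.042    -2.381
 terrestrial  1.211    -2.267
slope difference (terrestrial - aquatic) CI: (0.929, 1.577)
```

The interaction model wins decisively (the other models sit > 23 AICc units
away, averaged over the 50 tree resolutions): minimum prey mass rises with
predator mass for terrestrial species (slope ≈ 1.21) but not aquatic ones
(slope ≈ −0.04), and the slope-difference CI excludes 0. This mirrors the
generator's truth (the dataset was simulated with a terrestrial–aquatic
slope difference of 1.16 and λ = 0.62; with n = 20 the λ estimate is
imprecise).

```r
decompose_variance(tab, "min")
#> Variance decomposition, response 'min' (total 2.7952)
#>       source component percent
#>        order    0.0000    0.00
#>       family    0.0000    0.00
#>        genus    0.0000    0.00
#>         mass    0.7029   25.15
#>  environment    0.4072   14.57
#>     residual    1.6851   60.29

moments(tab, "all", "min")
#>   group response  n   mean median    min   max    sd range_kg  skewness ...
#> 1   all      min 20 -1.753 -2.195 -5.286 1.266 1.681    18.47 0.0001593
prey_span(tab, "all")
#> [1] 257.7604   # kg, max(prey_max) - min(prey_min)
```

The one-shot pipeline (`run_all(run_config(...))`) chains
validate → prune/resolve → PGLS model selection → variance components →
moments and writes CSV outputs plus a JSON manifest; a thin CLI wrapper
lives in `inst/scripts/preyscale.R`.

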