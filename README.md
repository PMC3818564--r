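# chalcomp

Phylogenetic comparative analysis of morphology and host use in parasitoid
wasps (Chalcidoidea) — and in any clade with a similar study design. The
package is aimed at comparative biologists who have a published phylogeny
(or several competing ones), a species-by-trait table mixing continuous
morphometrics, counts, and 0/1 ecological flags, and who want to ask: how
strongly is each trait structured by phylogeny, and which aspects of host
use predict morphology once phylogeny is accounted for?

## What it computes

**Tree assembly.** Published backbones rarely contain every study species.
`prune_to()` restricts a tree to the study set; `attach_sibling_halfway()`
adds a congener as a sibling with the branching point halfway along the
existing pendant branch; `graft_rescaled()` splices an intrageneric subtree
into a backbone, multiplying all subtree branch lengths by
`s = d_back / d_sub` so the shared reference species keeps its depth
exactly; `set_equal_branch_lengths()` handles sources published without
branch lengths; `ultrametricize_pl()` makes the assembled tree ultrametric
by penalized-likelihood rate smoothing.

**Phylogenetic signal.** For a continuous trait, Pagel's λ — the multiplier
of the off-diagonal elements of the Brownian variance–covariance matrix
`V` — estimated by maximum likelihood over `[0, 1]` with a likelihood-ratio
test against λ = 0 (`fit_lambda()`). For a binary trait, the Fritz–Purvis

```
D = (d_obs − mean_brownian) / (mean_random − mean_brownian)
```

where `d_obs` is the sum of sister-clade differences of nodal values and
the two means come from simulated nulls at the observed prevalence:
uniformly random assignment (D = 1, no signal) and a Brownian-threshold
model (D = 0); D < 0 means clumping stronger than Brownian (`fit_d()`).

**PGLS model selection.** `fit_pgls()` fits
`y = Xβ + ε, ε ~ N(0, σ²V(λ))` with λ estimated jointly by maximum
likelihood, and reports β ± s.e., R², and `AIC = 2k − 2 lnL`. Model
batteries compare each predictor against the null (intercept-only, or
body-size-only for antennal models) by the evidence ratio
`ER = exp(ΔAIC / 2)` (`model_battery()`, `evidence_ratio()`).

**Origins.** `count_origins_fitch()` counts the minimum number of
evolutionary origins of a binary trait by Fitch parsimony.

**Synthetic studies.** `synthetic_study()` generates a Yule tree plus a
trait table with the structure of the real data (Brownian log body length,
allometric log antennal area with slope 1.7, right-skewed host counts,
clumped host-use flags, the specialist rule), so every stage of the
analysis can be exercised and calibrated without any downloads.

## Worked example

```r
library(chalcomp)

study <- synthetic_study(sim_config(seed = 2026))   # 126 species
dat   <- add_log_traits(study$traits)

fit <- fit_pgls(dat, log_antennal_area ~ log_body_length, study$tree)
fit
#> PGLS fit: log_antennal_area ~ log_body_length
#>   lambda = 0.6135 (ML)
#>                 Estimate Std.Error
#> (Intercept)      -2.4051    0.0963
#> log_body_length   1.5767    0.0400
#>   R^2 = 0.926  lnL = 2.47546  AIC = 3.04908  n = 126
```

The slope (1.58 ± 0.04) is the allometric exponent of antennal area on body
length; the generating value is 1.7, and a slope of 2 would be isometry for
an area against a length. λ = 0.61 says the residual variation carries
intermediate phylogenetic signal.

```r
sig <- signal_battery(dat, study$tree, n_sim = 1000, seed = 2026)
dplyr::select(sig, trait, statistic, estimate, p_value, significant)
#>    trait                      statistic estimate  p_value significant
#>  1 log_body_length            lambda      1      1.55e-41 TRUE
#>  2 log_host_species           lambda      0      1   e+ 0 FALSE
#>  3 host_orders                lambda      0      1   e+ 0 FALSE
#>  4 plant_genera               lambda      0      1   e+ 0 FALSE
#>  5 residual_log_antennal_area lambda      0.614  5.33e-17 TRUE
#>  6 parasitoid                 D          -0.257  0        TRUE
#>  8 specialist                 D           1.15   8.92e- 1 FALSE
#> 10 para_sternorrhyncha        D          -0.0658 0        TRUE
#> ...
```

Morphology is strongly conserved (λ near 1), host-breadth measures carry no
signal (λ = 0; specialist D near 1), and the host-order flags are clumped at
or beyond the Brownian expectation (D ≤ 0) — the signal structure the
generator plants. Fitch origin counts for any flag:

```r
origins_battery(dat, study$tree, binary = "para_sternorrhyncha")
#>   trait               origins     n
#> 1 para_sternorrhyncha      13   126
```

`run_full(study_config(...))` chains the whole workflow — signal battery,
body-size and antennal-size model batteries, origin counts — for one or two
phylogenies and writes CSV tables plus a run log.

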