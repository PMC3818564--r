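---
title: "Methods: trees, signal, and PGLS model selection in chalcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trees, signal, and PGLS model selection in chalcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chalcomp implements the analysis pipeline of a phylogenetic comparative
study of parasitoid wasp morphology and host use: assembling a usable tree
from heterogeneous published sources, quantifying phylogenetic signal in
continuous and binary traits, regressing morphology on host-use predictors
with phylogenetically structured errors, and counting evolutionary origins
of host-use traits. This vignette documents the models, the conventions and
tunable parameters, the synthetic-data generator used for calibration, and
the known limitations.

## Tree assembly

Comparative analyses need one tree containing exactly the study species,
with branch lengths on a single scale. Published phylogenies rarely provide
this directly, so the package implements three explicit assembly rules:

* **Sibling insertion** (`attach_sibling_halfway()`): when a genus
  contributes two study species but the backbone carries only one, the
  missing species is attached as a sibling, with the split placed halfway
  along the existing pendant branch. Both siblings end at the same depth;
  no other depth changes.
* **Rescaled grafting** (`graft_rescaled()`): an intrageneric phylogeny
  sharing a reference species with the backbone replaces that species'
  pendant branch. Every subtree branch is multiplied by
  `s = d_back / d_sub` (backbone pendant length over subtree root-to-
  reference distance), so the reference depth is preserved exactly and the
  congeners inherit the backbone's scale. Subtrees without branch lengths
  are refused; the caller must first apply `set_equal_branch_lengths()`,
  which keeps the equal-lengths convention an auditable, deliberate step.
* **Ultrametricization** (`ultrametricize_pl()`): penalized-likelihood rate
  smoothing. Node ages `a` (root fixed at 1, tips at 0) and per-edge rates
  `r_k` maximize a Poisson-type branch log-likelihood
  `sum_k [x_k log(r_k t_k) − r_k t_k]` minus `smoothing` times a roughness
  penalty on ancestor–descendant rate differences, where `x_k` is the
  observed branch length and `t_k` the implied duration. The optimization
  is delegated to `ape::chronos(model = "correlated")`, which implements
  exactly this estimator; the two-tip case, where the constraints fully
  determine the ages, is solved directly. The smoothing weight defaults to
  10 and is exposed as a parameter; the original smoothing value for this
  study design is not recorded anywhere we could verify, and
  cross-validated selection of the weight is deliberately out of scope.
  Because all downstream statistics (λ, D, PGLS slopes, AIC differences)
  are invariant to a global rescaling of the covariance matrix — a property
  the test suite checks — the arbitrary root age of 1 is harmless.

Zero or missing branch lengths are replaced by `1e-8` times the tree height
before smoothing and covariance computation, keeping the objective finite
and the covariance positive definite. Polytomies are retained for
covariance computation (where they are valid) and resolved deterministically
with zero-length edges — a depth-neutral operation — before algorithms that
require binary trees (smoothing, Fitch counting, nodal averaging for D),
with a warning.

## Phylogenetic signal

### Continuous traits: Pagel's λ

Under Brownian motion the expected covariance of a trait across tips is
`σ²V`, with `V[i, j]` the shared root-to-MRCA path length. Pagel's λ
multiplies the off-diagonal of `V`: λ = 1 is the Brownian expectation, λ = 0
independence. `fit_lambda()` maximizes the profile log-likelihood

    lnL = −(1/2) [ n log(2π σ̂²) + log|V(λ)| + n ]

over λ ∈ [0, 1] with an intercept-only design, where β̂ and σ̂² are the GLS
profile estimates. The search is a 101-point grid pre-scan followed by
Brent refinement in the bracketing interval — deterministic,
derivative-free, and robust to the mild multimodality the profile can show.
Ties break toward 0 (so a star tree, where λ has no effect, reports 0), and
estimates at the upper bound are flagged `capped`; values above 1 are not
searched, matching the common bounds convention. The test against λ = 0 is
a likelihood-ratio test on the upper tail of χ²₁; because λ = 0 lies on the
boundary of the parameter space this is conservative by about a factor of
two, which we accept and document rather than adopting the 50:50 boundary
mixture.

### Binary traits: Fritz–Purvis D

`d_observed()` estimates nodal values bottom-up as the unweighted mean of
the two daughter values (tips carry their 0/1 states; branch lengths are
ignored, per the published algorithm) and sums the absolute daughter
differences over internal nodes. `fit_d()` scales this observed score
between its simulated expectations under two nulls that preserve the
observed prevalence exactly:

* random: states shuffled uniformly across tips (no signal; D = 1),
* Brownian threshold: a Brownian liability simulated on the tree, with
  state 1 assigned to the tips with the largest liabilities (D = 0).

Branch lengths enter only through the Brownian null. `n_sim` defaults to
1000 per null; p-values are raw tail proportions (no +1 correction):
`p_random` the fraction of random-null scores at or below the observed
score (departure from D = 1), `p_brownian` the fraction of Brownian-null
scores at or above it (departure from D = 0). D below 0 (stronger-than-
Brownian clumping) and above 1 arise naturally and are reported as-is.

## PGLS regression and model selection

`fit_pgls()` fits `y = Xβ + ε`, `ε ~ N(0, σ²V(λ))`, profiling β and σ² and
maximizing over λ with the same deterministic search as `fit_lambda()`
(λ can also be fixed). Conventions, each genuinely open and settled here
once:

* **Standard errors** use the unbiased scaling `σ̂² n / (n − p)` on
  `(XᵀV⁻¹X)⁻¹`; the ML σ̂² itself feeds the likelihood and AIC. This
  mirrors common GLS reporting and affects only the standard errors.
* **R²** compares the whitened residual sum of squares against an
  intercept-only GLS fit under the *model's own* λ̂, making it a pure
  association measure. The alternative (the null's own λ) would mix signal
  changes into R².
* **Parameter count** `k` = coefficients + 1 (σ²) + 1 if λ is estimated;
  `AIC = 2k − 2 lnL`. Within a battery every model shares the convention
  and the null also estimates λ, so evidence ratios are unaffected by the
  choice.
* **Predictors are not standardized**; 0/1 flags enter as dummies, so
  slopes stay in interpretable units.

`model_battery()` fits one model per predictor (plus an optional covariate
included in every model and in the null — body size, for antennal-size
batteries) and reports `ER = exp((AIC_null − AIC_model)/2)`. The numeric ER
is always retained; the display column shows a dash when the model does not
beat the null, mirroring the reporting convention of comparative tables.
Evidence ratios are recomputed from full-precision AICs, not from rounded
table values: rounded-AIC arithmetic reproduces printed ERs only when the
rounding happens to be self-consistent, and the tests assert the worked
examples only for such rows.

The signal of size-corrected antennal area is computed by first fitting the
allometric PGLS of log antennal area on log body length and then passing
the response-scale residuals (`residuals_of()`) to `fit_lambda()`.

## Synthetic-data generator

`synthetic_study()` emulates the *structure* of the study data — it makes
no attempt to match the real chalcidoid values beyond structure:

* a Yule tree (126 species by default; forward simulation with
  `Exp(j · birth)` waiting times, expected depth `sum(1/(2:n))`);
* log body length: Brownian motion, rate 0.25 (log-mm² per unit relative
  time), root 0.5 log mm — giving a realistic ~0.2–10 mm spread;
* log antennal area: intercept −2.45 + slope 1.7 × log body length + a
  λ-structured residual (λ 0.5, rate 0.02), so size-corrected antennal
  area carries intermediate signal;
* host-species counts: a lognormal latent (meanlog 1, sdlog 1.2) rounded
  up — strongly right-skewed, as in the real data; host-order counts
  increase stochastically with host breadth; plant-genus counts are an
  independent lognormal latent. These distributional parameters are
  explicit configuration, not estimates of the real data;
* binary host-use flags: Brownian-threshold (clumped) by default at
  configured prevalences (the documented counts are used where stated:
  20/126 egg parasitoids, 9/126 parasitizing non-sternorrhynchan
  Hemiptera); `para_hemiptera` is the union of the two suborder flags; the
  specialist flag is *derived* from the host-breadth rule (parasitoid with
  fewer than 10 host species in a single order), not simulated — which is
  why it emerges with essentially no phylogenetic signal while the
  host-order flags are strongly clumped, the same contrast the real study
  reports.

Multivariate-normal sampling uses the Cholesky factor of `σ²V(λ)` with a
diagonal jitter of `1e-10 × trace/n` on factorization failure (V(λ) can be
near-singular for λ → 1 with tiny terminal branches). All generators are
bit-reproducible under a seed.

What the generator does **not** emulate: measurement error in the
morphometrics, missing data, correlated evolution between host-use flags,
non-Brownian trait evolution (e.g. Ornstein–Uhlenbeck), and the
phylogenetic uncertainty of the real backbones. Tests passing on synthetic
data therefore demonstrate correctness of the estimators under their
generating models, not robustness to these real-data features.

## Calibration and problem sizes

The test suite and `scripts/acceptance.R` verify, among others: exact
worked examples of the AIC→ER arithmetic; mean ML λ ≈ 1 over 200 Brownian
traits on 128-tip Yule trees and median λ ≈ 0 after tip shuffling; mean
D ≈ 1 over 200 random and ≈ 0 over 200 Brownian-threshold binary traits
(prevalence 32/128, 1000 simulations per null); mean PGLS slope ≈ 2 over
200 isometric simulations on 126-tip trees; equivalence of PGLS with OLS on
star trees, with independent-contrasts regression at λ = 1, and of the GLS
likelihood with the direct multivariate-normal density; and exhaustive-
enumeration oracles for the change score, Fitch length, and covariance
matrix on small trees. These replicate counts and tree sizes were chosen so
Monte-Carlo error sits comfortably below the assertion tolerances while the
whole suite stays desk-scale.

## Numerical notes and limitations

* Degenerate fits (residual variance numerically zero) raise an error; the
  profile likelihood is unbounded there.
* `fit_d` errors when the two null means coincide (degenerate scaling),
  rather than dividing by ~0.
* The λ likelihood-ratio test's χ²₁ reference is conservative at the
  boundary (above).
* Polytomy resolution for D and Fitch is order-deterministic but
  arbitrary; how residual polytomies were resolved in the original
  published trees is not recorded, so counts on heavily polytomous trees
  should be read as the resolution-specific minimum.
* `ultrametricize_pl` inherits `chronos`' convergence behaviour; a
  non-ultrametric result (never observed in testing) raises an error
  carrying the achieved objective.
* No Blomberg's K, no Ornstein–Uhlenbeck models, no multi-state D, no
  phylogenetic logistic regression, no measurement-error models.
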