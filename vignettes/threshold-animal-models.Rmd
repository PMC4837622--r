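---
title: "Threshold-linear animal models for an ordinal trait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-linear animal models for an ordinal trait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedliab)
```

# The problem

White striping in broiler chickens is scored on an ordinal scale
(NORM < MOD < SEV). Genetic analysis of such a score uses the classical
threshold model: an unobservable, normally distributed *liability* underlies
the score, and a bird expresses category $k$ when its liability lies between
thresholds $t_{k-1}$ and $t_k$. With $m = 3$ categories there are $m - 1 = 2$
thresholds. Pairing the liability with one quantitative trait at a time in a
bivariate animal model yields the liability-scale heritability of the score
and its genetic correlation with the quantitative trait.

# Model

For each trait of the pair, the record of bird $l$ in hatch $i$ of sex $j$
reared by dam $k$ is

$$y_{ijkl} = \mu + H_i + S_j + c_k + a_l + e_{ijkl},$$

where $c_k$ is a common maternal-environment effect included only for traits
flagged for it (body weight in the motivating application) and $a_l$ is the
additive genetic effect. Stacking both traits,

$$\operatorname{Var}\!\begin{pmatrix} a_1 \\ a_2 \end{pmatrix} = A \otimes G,
\qquad
\operatorname{Var}\!\begin{pmatrix} e_1 \\ e_2 \end{pmatrix} =
\bigoplus_{k=1}^{n} R_k,$$

with $A$ the additive relationship matrix and $G$, $R$ the 2×2 genetic and
residual covariance matrices. Hatch is deliberately confounded with
generation (different hatch labels per generation); no separate generation
effect exists. A line fixed effect is *not* part of the default genetic
model, matching the model equation above; `model_spec(include_line = TRUE)`
adds one for sensitivity analysis. Intra-line analyses instead restrict the
records to one line (`lines =`) while keeping the complete pedigree.

## Identifiability

The liability scale has no intrinsic origin or unit. We fix $t_1 = 0$ and
$\sigma^2_{e1} = 1$; the overall mean $\mu_1$ and the second threshold $t_2$
remain free. This is the standard parameterization for a 3-category trait
and is recorded in chain-file headers.

## Priors

Fixed effects and thresholds have flat priors. $G$ has an inverse-Wishart
prior with $\nu_0 = \dim + 1$ and scale $0.1\,I$ — minimally informative
while keeping every draw positive definite. The maternal variance and the
conditional residual variance have scaled-inverse-chi-squared priors with
$\nu_0 = 1$, $s_0^2 = 0.1$; the unconstrained residual matrix of a
two-quantitative-trait model has the same inverse-Wishart form as $G$.
These are package choices: the reference threshold-model software used in
the field does not document its priors, so no claim of identity is made.
With thousands of records the likelihood dominates these priors;
`gibbs_run(prior_scale = )` rescales the prior scale matrices (e.g. 0.1
and 10) so prior sensitivity can be reported by refitting.

# The Gibbs sampler

Each iteration performs, in order:

1. **Data augmentation.** Every liability is redrawn from a normal
   truncated to its category's interval, with mean shifted by the residual
   regression on the co-trait, $\mu_1 + (\sigma_{e12}/\sigma^2_{e2})e_2$,
   and conditional variance $\sigma^2_{e1} - \sigma^2_{e12}/\sigma^2_{e2}$
   (inverse-CDF method). Records missing one trait have that trait imputed
   from the same conditional without truncation, which integrates the
   missing residual out exactly; birds with no record at all enter only
   through $A$.
2. **Threshold.** $t_2$ is drawn uniformly on (max liability among MOD,
   min liability among SEV) — its full conditional given the liabilities.
3. **Location effects.** Scalar fixed-effect and maternal coefficients,
   then animal-wise 2×2 blocks of breeding values, are drawn from their
   normal full conditionals. Breeding-value conditionals use the sparse
   $A^{-1}$ neighborhoods and the current $G^{-1}$, so each update costs
   O(non-zeros in the row). Residuals are maintained incrementally.
4. **Variances.** $\sigma^2_c$ from its scaled-inverse-chi-squared
   conditional; $G$ from the inverse-Wishart conditional with scale
   $S_0 + a^\top A^{-1} a$; $R$ under the $\sigma^2_{e1} = 1$ constraint by
   sampling the residual regression $b = \sigma_{e12}$ and conditional
   variance $\tau^2$ from their conjugate conditionals and recomposing
   $\sigma^2_{e2} = \tau^2 + b^2$.

The core is compiled (RcppArmadillo) but consumes R's RNG stream, so a run
is a pure function of the data and `mcmc_config(seed = )`. Univariate
models are the same machinery with the second trait switched off; a
Gaussian first trait replaces the truncation by the observed record, which
is how the sampler is validated against direct mixed-model-equation
solutions.

## Initialization

Initial liabilities are placed at the normal quantiles of the mid-points of
each category's cumulative frequency band, rescaled so $t_1 = 0$, with an
assumed liability SD of $\sqrt 2$ (a heritability of one half); $t_2$
starts at the matching quantile distance. Fixed effects start at the least
squares solution on the initialized responses, breeding values at zero,
genetic variances at half the phenotypic variance. Initialization from the
observed category frequencies matters because the threshold's uniform
conditional moves $t_2$ by only O(1/n) per iteration: a frequency-based
start places it near its stationary region so the burn-in is spent
exploring rather than travelling. This slow threshold random walk is the
best-known mixing limitation of single-site threshold-model samplers and is
the reason the reference schedule is long.

## Schedules

The reference schedule is a single chain of 100,000 iterations, 20,000
discarded as burn-in and every 20th draw kept — exactly 4,000 retained
draws. Test and example runs in this package use shorter documented
schedules (e.g. 20,000/4,000/10 for recovery studies at ~3,000 birds,
a few hundred iterations for structural checks on ~300 birds); these sizes
were chosen so that the whole validation suite runs on a desktop in
minutes while posterior SDs remain small enough for 2-SD recovery checks
to be informative.

# Pedigree machinery

`additive_relationship()` builds dense $A$ by the tabular method;
`a_inverse()` builds sparse $A^{-1}$ directly from Henderson's rules with
Mendelian-sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$, inbreeding
coefficients by the Meuwissen–Luo algorithm. Inbreeding *is* accounted for:
closed selected lines accumulate non-trivial $F$ over six generations, and
ignoring it would misweight late-generation Mendelian-sampling terms.
Unknown parents are treated as unrelated base-population founders — no
genetic groups, since the design has a single base population. Individuals
are addressed by identifier throughout; matrix row order is the pedigree's
topological order and is never exposed as an interface.

# The synthetic-data generator

`simulate_population()` emulates the two-line divergent-selection design:
a common base generation; within each line, truncation selection on the
quantitative trait's own phenotype (mass selection), high in one line and
low in the other; discrete generations with one hatch label per
generation; breeding values propagated as parent average plus
Mendelian-sampling deviation with variance
$0.5(1 - (F_s + F_d)/2)\,G$; one maternal-environment draw per dam;
liability thresholded into NORM/MOD/SEV. Defaults are scaled to the
motivating population: base of 1,640 birds plus six generations of
2 × 85 dams × 9 offspring (~10,800 birds, ~380 sires, ~1,020 dams), ordinal
scoring restricted to generations 5–6, genetic and residual parameters
giving a liability heritability of 0.65, and thresholds placed so that
roughly 37% of an unselected population is MOD and 14% SEV.

What the generator does *not* emulate: the real breeding scheme's
family-structure rules and overlapping hatches within generation, BLUP- or
family-based parent selection, natural selection/mortality, and any
non-normal trait behaviour. Passing recovery tests therefore show that the
estimation machinery is correct under the model's own assumptions — they
cannot certify behaviour under model misspecification on real data.

Two simulator subtleties found during validation are worth recording. The
offspring–midparent regression equals $h^2$ only when the parents come from
the unselected base: later generations add Bulmer-effect variance reduction
and line structure, which bias the pooled regression. And with few hundred
birds the split of a trait-pair covariance into genetic and residual parts
is weakly identified — single small datasets can put compensating posterior
mass on $\sigma_{g12}$ and $\sigma_{e12}$ — so null-covariance calibration
is asserted over replicate datasets, and headline recovery at ~3,000 birds.

# Posterior summaries and diagnostics

`summarize_chain()` reports the posterior mean, the posterior SD (labelled
the standard error of the estimate, following the field's reporting
convention), and a 95% equal-tail interval; `significant` marks intervals
excluding zero, reproducing the operational rule used in the motivating
study. A highest-density interval is available (`hdi = TRUE`). The
heritability denominator includes the maternal variance for the maternal
trait (the phenotypic variance is then genetic + maternal + residual);
`h2_per_draw(include_maternal = )` exposes both conventions.

`dempster_lerner()` converts a liability-scale heritability to the
observed scale, $h^2_{obs} = h^2_{lia}\, z^2 / (p(1-p))$ with $z$ the
standard-normal density at the incidence threshold; the factor is symmetric
in $p \leftrightarrow 1-p$ and equals $2/\pi$ at $p = 0.5$.

`heidelberger_welch()` implements the stationarity (Cramér–von Mises on
the Brownian-bridge transform, discarding initial 10% increments up to
50%) and halfwidth tests. The spectral density at frequency zero is
estimated by an AIC-selected autoregressive fit (`stats::ar`), the same
estimator family used by the established MCMC-diagnostic packages; the
halfwidth rule compares the asymptotic 95% halfwidth of the mean to 10% of
the mean by default. Multi-chain diagnostics are out of scope because the
reference analysis runs a single chain.

# Numerical choices

* Truncated-normal draws use the inverse-CDF method; intervals with
  essentially zero probability mass (far tails) fall back to the nearest
  admissible point and are counted (`n_clamped` attribute).
* Aliased fixed-effect levels are handled by corner constraints (reference
  level dropped when an intercept is present); factors with a single
  observed level drop out of the design.
* The inverse-Wishart draw uses the Bartlett decomposition; $2 \times 2$
  breeding-value updates use a hand-rolled Cholesky.
* The phenotypic-stage letter display enumerates maximal
  non-significant cliques exhaustively (the number of means per family is
  small); Tukey–Kramer rather than plain Tukey because the design is
  unbalanced. Drip loss is log-transformed at fitting time, never in
  storage.
* An optional, off-by-default outlier filter (|value − median| > 5 MAD,
  configurable) logs every removal; the original analysis pipeline's
  outlier rule is unpublished, so reproducibility is preferred over
  guesswork.

# Known limitations

* At most two traits per model; maternal effects are environmental, not
  genetic; no alternative samplers or model-comparison tools.
* The free threshold mixes slowly (O(1/n) moves), inflating
  autocorrelation for $t_2$-adjacent parameters on large datasets; the long
  reference schedule compensates.
* Genetic/residual covariance splitting is weakly identified in small,
  shallow pedigrees; interpret per-dataset posteriors accordingly.
* The simulator's mass selection is a simplification of any real breeding
  scheme; realized selection differentials are recorded per generation so
  users can audit the selection pressure actually applied.
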