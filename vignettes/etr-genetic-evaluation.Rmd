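---
title: "Genetic evaluation of eye temperature at rest: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of eye temperature at rest: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etrgen)
```

## The trait and the question

Eye temperature at rest (ETR, °C), the maximum temperature in an ocular
region of interest of an infrared image, is a non-invasive proxy for a
horse's basal reactivity: more reactive animals run warmer eyes through
sympathetically innervated capillary beds. In a composite sport-horse
population, coat color is entangled with reactivity twice over — coat-color
genes have pleiotropic effects on temperament, and coat classes may differ
in residual (environmental) variability. The pipeline in this package asks
three questions of an ETR dataset:

1. Which environmental classifications (coat, sex, age class, competition
   location, breed group) shift mean ETR, and how do the levels separate?
2. Does ETR predict show-jumping rank?
3. How heritable is ETR, and do two genetic parameterizations of the coat
   effect — a mean-level one and a variance-level one — select the same
   animals?

Because the motivating data belong to a breeders' association, the package
ships a synthetic-data generator with known true parameters; every claim
the pipeline makes is tested against that ground truth.

## Phenotype-side statistics

The trait passes a Shapiro–Wilk gate (`shapiro_wilk_gate()`); a failure is
logged, not fatal, since the downstream F-tests are robust at the sample
sizes involved. Each classification is tested by a **one-way** GLM
(`one_way_glm()`): $F = MS_{between}/MS_{within}$ on $(k-1,\,n-k)$ degrees
of freedom, coded `n.s.` / `*` / `**` / `***` at 0.05/0.01/0.001. The
coat-by-effect interaction (`interaction_glm()`) is the extra-sum-of-squares
F between the additive and crossed two-factor linear models. We deliberately
test one effect at a time (plus the interaction row) rather than one
multi-factor model: with per-effect one-way tests the Type I/III
sum-of-squares question never arises, at the cost of effects absorbing each
other's variance — a trade made for transparency of the reported grid.

Level separation uses least-squares means (equal to arithmetic means in the
one-way layout) with Duncan's multiple range test (`duncan_mrt()`): the
critical range for a span of $p$ ordered means is
$R_p = q_{\alpha_p}(p, df)\sqrt{MS_{within}/n_h}$ with the protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$, studentized-range quantiles from
`qtukey()`, and $n_h$ the harmonic mean of level counts (the classical
unbalanced extension; the balanced theory does not define one). Levels
sharing a letter do not differ at $\alpha$.

Rank association is Spearman's $\rho$ on mid-ranks with the two-sided
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — adequate from a few
dozen pairs upward; an exact permutation p-value would only matter below
$n \approx 10$.

## The animal models

Both genetic models are the single-trait animal model
$$\mathbf y = \mathbf X\mathbf b + \mathbf Z\mathbf u + \mathbf e,\qquad
\mathbf u \sim N(\mathbf 0, \mathbf A\sigma_u^2),\quad
\mathbf e \sim N(\mathbf 0, \mathbf R),$$
with $\mathbf A$ the numerator relationship matrix over the full pedigree.
They differ in how coat color enters:

* **MGG** (genetic groups): fixed effects age class (3), sex-within-coat
  (8), location (3), breed group (5); $\mathbf R = \mathbf I\sigma_e^2$;
  unknown parents are assigned to 5 genetic groups keyed by the coat color
  recorded for the most-ancestral known animal of the founder line
  (chestnut, bay, black, gray, unknown). Groups let founder lines of
  different coat origins have different genetic means.
* **MHRV** (heterogeneous residual variance): fixed effects age class, sex,
  coat, location, breed group; no groups; $\mathbf R$ diagonal with one
  $\sigma_{e,k}^2$ per coat class of the measured animal. Heritability
  becomes class-specific: $h^2_k = \sigma_u^2/(\sigma_u^2+\sigma_{e,k}^2)$
  with the single shared $\sigma_u^2$.

### Pedigree machinery

`validate_and_renumber()` topologically sorts the pedigree (cycles are an
error; unlisted parents become founders with a warning, or an error in
strict mode). Inbreeding uses the Meuwissen–Luo recursion; the sparse
$\mathbf A^{-1}$ (`a_inverse()`) is assembled from per-animal contributions
with inbreeding-adjusted mendelian-sampling variances and verified in the
tests against dense inversion of the tabular $\mathbf A$ and against
gene-dropping Monte Carlo.

Genetic groups use the Quaas–Pollak/Westell phantom-parent augmentation
(`a_inverse_with_groups()`): the coefficient matrix gains one equation per
group, and missing-parent slots contribute to group rows exactly as a
parent would. Algebraically the augmented matrix equals
$[\mathbf A^{-1}, -\mathbf A^{-1}\mathbf Q; -\mathbf Q'\mathbf A^{-1},
\mathbf Q'\mathbf A^{-1}\mathbf Q]$ with $\mathbf Q$ the group gene
fractions — the tests check this block identity directly. Animal solutions
of the augmented system are total breeding values (group mean included).
Two open choices were resolved as follows: both phantom slots of a founder
share one group (the source analysis does not distinguish sire and dam
paths), and a founder with unrecorded coat maps to the "unknown" group — we
never infer a coat from descendants, to avoid inventing an inference rule.

With any fixed effect fully coded, the augmented system has exactly one
null direction (a constant added to every group and animal solution and
subtracted from the fixed effects), so `build_mme()` absorbs the last
non-empty group — its solution is pinned at 0 and the others are deviations
from it. Empty groups are dropped outright.

### Gibbs sampler

`gibbs_run()` is a systematic-scan Gibbs sampler. All location parameters
(fixed effects, breeding values, group effects) are one Gaussian block:
their joint full conditional has precision matrix equal to the mixed-model
coefficient matrix, so the draw is a sparse Cholesky solve plus a
triangular solve of white noise — exact, and far better mixing than
single-site updates at no extra asymptotic cost. Variances have scaled
inverse chi-square full conditionals:
$\sigma_u^2 \mid \cdot \sim (\,\mathbf u'\mathbf A^{*-1}\mathbf u +
\nu_u S^2_u)/\chi^2_{\nu_u+q}$ with $q$ the number of pedigree animals, and
$\sigma_{e,k}^2 \mid \cdot \sim (SSE_k + \nu_e S^2_e)/\chi^2_{\nu_e+n_k}$
per residual class.

Priors default to the flat limit $\nu = -2$, $S^2 = 0$ (uniform on the
variance). This matters: at a few hundred records the posterior spread of
$h^2$ is prior-sensitive, and a proper weakly informative choice will
shrink the reported intervals. The default chain settings are 100,000
iterations, 10,000 burn-in, thinning 10 — exactly 9,000 saved samples —
with shorter demo settings used throughout the scripts. Convergence
reporting (`convergence_report()`) gives the initial-positive-sequence
effective sample size and a split-chain potential-scale-reduction
statistic; both are advisory. Heritability chains are computed per saved
sample and summarized by mean, sd, median and the shortest-interval HPD.

`blup_solve()` solves the same equations at fixed variances; the tests pin
the fixed-variance sampler to it within Monte-Carlo error, which validates
the location block (including the Cholesky permutation handling) and the
system assembly independently of the variance updates.

### Breeding-value report

Raw EBVs (posterior means of $\mathbf u$) are mapped to the conventional
80–120 scale by $s = 100 + 5(u - \bar u)/\hat\sigma_u$, clipped to the
interval: one genetic standard deviation is 5 points and ±4 sd span the
scale, so the population mean is exactly 100 before clipping. The mapping
is not dictated by the scale's definition; a min-max variant is available
(`method = "minmax"`). Selection takes the top `floor(0.20 n)` animals by
standardized value (ties broken by animal id), and
`model_coincidence()` counts per-coat overlap of the MGG and MHRV
selections, reporting the percentage on the MGG group size (the base is a
reporting convention, not an estimate, so the symmetric Jaccard index is
emitted alongside). The 20% is taken over all evaluated animals, not
within coat groups.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study population: 471
phenotyped animals inside a ~2,000-animal, 3-generation pedigree; coat
shares 16.6% gray, 11.3% chestnut, 51.6% bay, 20.5% black; age-class
shares 10.6/13.2/76.2%; sex shares 66/34; location shares 27.2/46.9/25.9%;
breed-group shares 9.6/5.9/29.9/43.3/11.3%; $\sigma_u^2 = 0.186$ with
$\sigma_e^2 = 0.736$ (homogeneous regime) or $\sigma_u^2 = 0.201$ with
per-coat residuals 0.82/0.88/0.98/0.72 (heterogeneous regime); target
ETR-rank correlation 0.11.

Choices the source setting leaves open, fixed once here:

* **Fixed-effect level means** (°C, deviations from a 36.0 base): gray
  −0.50 and black +0.15 among coats, youngest +0.30, females +0.20,
  south lowest among locations, BG4 −0.10 below the other breed groups.
  Only the orderings are anchored in the emulated population; the sizes
  were chosen so the significance pattern is reproducible at $n = 471$
  (e.g., the coat F-test clears $p < 0.001$ in the large majority of
  seeds) without being caricatures. An optional sex-by-coat crossover
  (`interaction_sex_coat`) generates interaction signal on demand.
* **Mating scheme**: discrete generations, random mating, with a
  per-generation active stallion pool (default 60). Horse studbooks are
  strongly polygynous, and the resulting paternal half-sib families carry
  most of the heritability information; with unrestricted mating a
  600-record dataset determines $h^2$ only to about ±0.09 (likelihood
  level), against roughly ±0.05 under the default pool.
* **Coat inheritance**: independent draws from the coat frequencies by
  default — downstream models treat coat as a label, not a genotype — with
  an optional parent-conditioned transmission table for realism.
* **Breeding values**: recursive mendelian sampling,
  $u_i = \tfrac12 u_s + \tfrac12 u_d + m_i$ with
  $Var(m_i) = \tfrac12\sigma_u^2(1 - (F_s+F_d)/2)$, so $Var(\mathbf u) =
  \mathbf A\sigma_u^2$ exactly (checked against the tabular $\mathbf A$ by
  simulation).
* **Ranks**: a Gaussian copula on the overall normal scores of ETR with
  latent correlation $r = 2\sin(\pi\rho_s/6)$, ranked within events of at
  most 72 entrants; only the observed correlation is specified by the
  emulated design, not a mechanism, and the copula is the least-committal
  construction hitting it.

What the generator does **not** emulate: weather and humidity covariates,
repeated measures per horse, non-random allocation of horses to events,
coat-linked fixed-effect confounding (e.g., gray horses clustering in one
region), selection or assortative mating in the pedigree, and measurement
error structure of the camera. Tests passing on this generator therefore
demonstrate correctness of the estimation machinery under the stated
model, not robustness of the scientific conclusions to those real-data
complications.

## Problem sizes and numerical choices

The test suite and the acceptance analysis run scaled-down chains chosen as
a compromise between Monte-Carlo error and turnaround: recovery
experiments use 1,500-animal pedigrees with 600 phenotyped records and
6,000-iteration chains (2,000 burn-in, thinning 10), and the heritability
recovery is judged on the **mean posterior-mean $h^2$ across 20 replicate
datasets**, because a single 600-record realization determines $h^2$ only
to ±0.05–0.09 whatever the chain length — averaging replicates measures
the estimator, not one dataset's luck.

Smaller numerical decisions, recorded so nobody has to reverse-engineer
them: the location block is sampled through a permuted sparse Cholesky
factorization updated in place each iteration (the symbolic analysis is
reused); the HPD interval is the shortest window over the sorted saved
samples containing at least 95% of them; a degenerate (zero-spread) EBV
vector standardizes to all-100; ties in selection break by animal id;
residual classes are the measured animal's own coat (an "unknown" coat
never occurs among measured animals); and ANOVA drops empty levels with a
warning but refuses to test fewer than two.

## Known limitations

* The flat variance priors make small-sample posterior means of $h^2$
  mildly sensitive to the prior; REML point estimates on the same data sit
  a few hundredths lower on average.
* Group solutions under MGG are deviations from the absorbed reference
  group; absolute group means are not identified when fixed effects are
  present (this is a property of the model, not the code).
* The Duncan procedure controls neither FWER nor FDR in the modern sense;
  it is implemented for fidelity to the emulated analysis, not as a
  recommendation.
* Chains mix slowly in $\sigma_u^2$ at small $n$ (effective sample sizes
  of a few percent of saved draws are typical); the convergence report
  should be consulted before quoting posterior standard deviations.
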