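---
title: "Corrected cross-cultural regression: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected cross-cultural regression: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cross-cultural datasets — one row per society or nation state — violate
the independence assumption of ordinary regression in three distinct
ways.  Societies are related by descent, so residuals of close relatives
are correlated (Galton's problem).  Societies close in space share
environment, history and contact, so residuals are spatially
autocorrelated.  And cultural variables covary with each other and with
environmental gradients (most notoriously latitude), so a regression of
one trait on one exposure can be significant without any direct link
between them.  Ignoring these produces inflated degrees of freedom,
distorted parameter estimates, and confident p-values for incidental
associations.

`crosscult` implements a GLS framework in which all three problems are
addressed explicitly: the residual covariance is constrained to a linear
mixture of a *phylogenetic similarity* matrix and a *spatial similarity*
kernel, the mixture being estimated by maximum likelihood together with
the regression coefficients; and covariation is handled procedurally, by
a staged model-comparison pipeline ("winnowing") that eliminates
predictors whose apparent effect is explained by relatedness, proximity
or a covarying variable.

## The cultural hierarchy and phylogenetic similarity

There is no global phylogeny of cultures, so relatedness is proxied by
the taxonomy of each society's dominant language.  A taxonomy gives
topology but not branch lengths; unitary branch lengths would assert
that every sister pair is equally similar, which a small non-random
sample of societies clearly violates.  Node heights are therefore
rescaled from two ingredients: a relative clade age $C \in (0, 1]$
(supplied per clade, proportional to the age of the language family
relative to the root), and the classification depth of each node.  A
node housing languages at classification level $L_s$ of a clade with
maximum level $L_c$ is placed, in raw units, at

$$(L_c - L_s) \times C.$$

The source formulation leaves these within-clade units arbitrary; to
make heights commensurable across clades we divide by $L_c$, so that
each clade ancestor sits exactly at height $C$ and tip-level nodes at 0
on a tree with root height 1.  This preserves both stated constraints
(clade-root height proportional to clade age; within-clade depth
proportional to classification level) while fixing the relative scale
across clades, which the raw formula leaves undefined.

Two further conventions close the construction.  Clades join a single
root at height 1 — no structure between language families is assumed.
Distinct societies with *identical* classification paths (for example,
two states sharing a dominant language) would make the similarity
matrix exactly singular if attached at height 0; they attach instead to
a common ancestor at $C / (2 L_c)$, half the smallest positive level
spacing of their clade.  Multifurcations are kept as-is; no arbitrary
binary resolution is imposed.

Phylogenetic similarity is then the Brownian-motion correlation implied
by the tree: $P_{ij} = 1 - h(\mathrm{MRCA}(i,j))$, the fraction of the
root-to-tip path a pair shares.  Pairs in different clades share
nothing ($P_{ij} = 0$); the matrix has unit diagonal.

## Spatial similarity

Distances are haversine great-circle distances between society
centroids on a sphere of radius 6371 km; centroid coordinates are
inputs (no GIS processing happens here).  Spatial similarity is a
Gaussian kernel

$$S_{ij} = \exp\!\left(-\left(d_{ij}/\sigma_s\right)^2\right),$$

with the length-scale $\sigma_s$ (km) estimated by maximum likelihood.
The parameterization $\exp(-(d/\sigma)^2)$ was chosen over the
equivalent $\exp(-d^2/(2\sigma^2))$ family; the two differ only by a
$\sqrt{2}$ rescaling of $\sigma_s$, which is why the formula is stated
wherever $\sigma_s$ is reported.  Gaussian kernels of *geodesic*
distance are not guaranteed positive definite on the sphere, so kernel
matrices are repaired by flooring eigenvalues at $10^{-8}$ and
renormalizing to a correlation matrix; the repair is recorded on the
returned object.  During fitting, $\sigma_s$ is searched on a
log-spaced range from 1 km to twice the largest observed distance.

## The GLS model

For response $y$ and design matrix $X$ over $n$ societies, the model is

$$y = X\beta + \varepsilon, \qquad
\varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2 V\right),$$

with the correlation structure constrained to a linear mixture.  Two
mixtures are offered:

* **nugget mode** (default): $V = w_p P + w_s S + (1 - w_p - w_s) I$,
  with $w_p, w_s \ge 0$, $w_p + w_s \le 1$.  The identity (nugget)
  component represents unstructured noise; OLS is nested at
  $w_p = w_s = 0$, so the corrected log-likelihood can never fall below
  the uncorrected one, and the contribution statistic (below) is
  non-negative up to optimizer slack.
* **paper mode**: $V = w_p P + (1 - w_p) S$.  The two structured
  similarities exhaust the mixture; OLS is *not* nested, and the
  contribution statistic can be negative (a worse constrained fit).
  The published analysis this package generalizes reports negative
  contributions for one variable, which is reproducible only under a
  mixture of this kind; since the exact linear function used there is
  not printed, both modes are provided and logged.

For fixed $(w_p, w_s, \sigma_s)$ the remaining parameters have closed
forms — $\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ and the ML
variance $\hat\sigma^2 = r^\top V^{-1} r / n$ — so the likelihood is
profiled and only three parameters are searched numerically.  The
search is a derivative-free simplex (Nelder–Mead) over transformed
coordinates (logistic for the weight simplex, log-scaled for
$\sigma_s$), restarted from five fixed, spread-out grid points, with
objective tolerance $10^{-8}$.  The multi-start grid is deterministic,
so fits are reproducible without any RNG involvement.

Coefficient standard errors are
$\sqrt{\hat\sigma^2 \,\mathrm{diag}\!\left((X^\top V^{-1}X)^{-1}\right)}$
and t-tests use $n - k$ degrees of freedom — deliberately *not*
penalized for the estimated covariance parameters, matching the
degrees of freedom convention of the source analysis.  A consequence,
visible in the calibration results below, is that the corrected test is
mildly anticonservative at moderate $n$ (rejection rate near 0.07–0.09
at nominal 0.05 for $n = 60$): the price of estimating three covariance
parameters by ML on the same data.  Missing data are handled by
listwise deletion per model; a $\hat\sigma^2$ floor of $10^{-12}$
guards exact-fit degeneracy; variables enter on their raw scales.

The overall contribution of relatedness and proximity to a model's fit
is summarized by

$$1 - \frac{\log L_{\text{corrected}}}{\log L_{\text{uncorrected}}},$$

which is 0 when structure adds nothing and grows as the corrected model
absorbs residual structure.

## Model comparison and the winnowing pipeline

Nested models are compared by likelihood ratio, $2\,\Delta \log L$
against $\chi^2_{df}$, where $df$ counts added regression coefficients
only — covariance parameters are re-estimated in both models and not
counted.  Non-nested models are compared by AIC,
$2(k + q) - 2\log L$ with $q$ the number of free covariance parameters
($\sigma^2$ plus $w_p, w_s, \sigma_s$ in nugget mode; $\sigma^2$ alone
for OLS); a difference greater than 2 is treated as meaningful support
and differences within 2 as equivalent explanatory power.  Covariation
among focal variables is screened by tie-corrected Kendall $\tau_b$
with normal-approximation p-values.

The pipeline then runs three stages with a drop-forward rule (a
variable dropped at any stage is never fitted again):

1. **Univariate screen.**  Each focal (cultural) variable is regressed
   on each exposure (parasite-load) measure, uncorrected and corrected.
   Variables with no significant corrected association against any
   exposure are dropped.  Significance gates use $\alpha = 0.05$ by
   default, with Bonferroni flags (0.05/m, the published analysis used
   m = 16, hence the quoted p < 0.003) reported alongside rather than
   used as the gate — mirroring the dual reporting of the source.
   Whether retention requires one or both exposure measures is
   configurable; the default is "any".
2. **Covariation.**  For each survivor, a corrected model on its
   significantly correlated focal covariates is compared, by LRT, with
   the same model plus the exposure.  Only combinations already
   significant (stage 1, and the Kendall screen) are tested; a survivor
   with no correlated covariates passes through untested.
3. **External races.**  Each remaining variable is raced against
   configurable covariate sets (gradient, biodiversity, population, and
   their combination): (a) LRT of covariates-only versus
   covariates-plus-exposure, and (b) AIC of the covariate-link model
   against the direct exposure-link model.  The exposure is retained
   for a variable only if no covariate set explains the association
   under either race.  A separate utility prunes covariates of the
   exposure itself (removing each and testing the loss of fit), the
   analogue of asking which environmental variables explain parasite
   load beyond latitude.

## The synthetic benchmark

The generator emulates the statistical structure of a 50-state
cross-cultural study without reproducing any real geography or
language family: a random prefix-tree taxonomy (2–5 classification
levels per clade, clade ages uniform on (0.2, 1]), coordinates
clustered by clade (inducing the correlation between relatedness and
proximity that real states show), and traits drawn from
$\mathcal{N}(X\beta, \sigma^2 V)$ via an eigendecomposition
factorization — the same repair-tolerant route the fitting side uses.

Study conditions are fixed in `sim_defaults()` (a deliberate single
versioned location): $n = 60$ societies in 8 clades, true mixture
$w_p = 0.4$, $w_s = 0.3$, $\sigma_s = 2000$ km, $\sigma^2 = 1$.  Sixty
societies matches the scale of the published state-level datasets this
emulates (50 states); 2000 km makes the kernel informative at
continental distances while leaving between-cluster contrasts.  Four
scenarios wire a parasite-like exposure (PAR), three cultural-like
focal traits (C1–C3) and three covariates (LATG, the observable
standardized absolute-latitude gradient; BIO, biodiversity-like,
loading 0.8 on the gradient; POPL, unstructured):

* *direct*: PAR → C1 with effect 0.8;
* *covariation*: PAR → C1, and C2 = 0.9 C1 + noise (no direct link);
* *confounded*: the gradient drives both PAR and C1 (loading 1.2), no
  direct link;
* *null*: no links.

Effect sizes were calibrated once, by pilot simulation, so that each
scenario's verdict is reached in at least ~80% of seeds at these
conditions: 0.8 gives the corrected univariate test power above 0.9 for
the direct edge at $n = 60$; 0.9 makes the covarying trait reliably
enter (and then fail) stage 2; 1.2 makes the confounded association
survive stage 1 often enough to be dispatched at stage 3.  The residual
~10–20% of wrong verdicts is dominated by a single mechanism: the
corrected test's mild anticonservativeness lets a noise trait through
stage 1 in roughly 8% of fits, and a fraction of those survive the
stage-3 races.  This is a property of the method at $n = 60$, not of
the generator, and it is the same leakage an analyst would face on real
data of this size.

What passing these scenario tests shows — and what it does not: the
pipeline reliably distinguishes direct effects, covariation artefacts
and gradient confounds *under the generator's assumptions* (Gaussian
traits, correctly specified covariance family, missingness completely
at random, a single dominant gradient).  Real cross-cultural data
violate all of these to some degree: traits are often ordinal or
bounded, borrowing is not Brownian, the spatial kernel is at best an
approximation, and state-level sampling is geographically biased.  The
synthetic results bound what the statistics can do when its own
assumptions hold; they do not certify conclusions about any particular
empirical dataset.

## Numerical choices and degenerate inputs

* Eigenvalue floor $10^{-8}$ for indefinite kernels, followed by
  correlation renormalization (preserves PSD *and* the unit diagonal).
* Cholesky is attempted first everywhere; the eigendecomposition repair
  runs only on failure, keeping the inner optimization loop cheap.
* Identical classification paths attach at $C/(2L_c)$ (nonsingularity);
  a taxonomy in which *every* pair shares at least half its history
  triggers a non-identifiability warning.
* Collinear designs are rejected with the offending columns named
  (condition number $> 10^{10}$); exact fits floor $\hat\sigma^2$ at
  $10^{-12}$ with a warning rather than diverging.
* LR statistics within $-10^{-6}$ of zero are clamped to 0 (optimizer
  slack); larger negatives raise an error, since they indicate
  non-nested misuse.
* Problem sizes used by the test suite and the acceptance script —
  $n = 60$ and $n = 100$, 50 seeds for recovery and scenario studies,
  500 replicates for the type-I calibration — were chosen to keep the
  Monte-Carlo error of each checked quantity well inside its decision
  band.

## Known limitations

* The covariance mixture is linear in two fixed similarity matrices;
  it cannot represent, e.g., trait-specific tree transformations
  (Pagel's lambda on a per-trait basis) beyond what the weights absorb.
* REML is not offered; all likelihoods are ML, so variance estimates
  are biased low in small samples and the coefficient tests inherit
  mild anticonservativeness (quantified above).
* The winnowing verdicts are decision procedures, not causal
  identification: "explained by covariates" means the exposure adds no
  likelihood beyond that covariate set at the chosen thresholds,
  nothing stronger.
* Kendall screening uses pairwise-complete observations, which can use
  different society subsets per pair when missingness is appreciable.
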