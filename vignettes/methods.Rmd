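---
title: "Methods: spin-test and PLS correspondence for parcellated cortical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin-test and PLS correspondence for parcellated cortical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpls)
```

## The problem

Studies that relate a cortical phenotype map — here, the parcel-wise
association between body-mass index (BMI) and cortical thickness — to
molecular and cognitive annotation maps face two statistical obstacles.
First, brain maps are spatially autocorrelated: neighbouring parcels carry
similar values, so a naive permutation test that shuffles parcel labels
wildly overstates significance. Second, annotation matrices (regional
expression of thousands of genes, activation likelihoods of a hundred-plus
cognitive terms) are far wider than the 62 parcels of the
Desikan–Killiany–Tourville (DKT) scheme, so single-map correlations must
give way to latent-component methods with their own permutation and
resampling inference.

`spinpls` implements that full pipeline — covariate-adjusted obesity-map
construction, spin permutation nulls, Pearson correlation batteries with
FDR, single-response partial least squares (PLS) with spin-based component
significance and bootstrap-ratio feature reliability, and hypergeometric
overrepresentation of selected gene lists — together with a synthetic-data
generator that emulates every input, because the cohort and atlas data such
studies use (multi-site thickness tables, donor microarray expression,
receptor PET, meta-analytic term maps) are controlled-access or externally
curated.

## Obesity maps

For each parcel $p$, ordinary least squares fits

$$\text{thickness}_{ip} = \beta_{0p} + \beta_p\,\mathrm{BMI}_i +
\gamma_p^\top z_i + \varepsilon_{ip},$$

with $z_i$ a shared covariate roster (age, sex, imaging site, education,
socioeconomic status; categorical covariates as indicator terms, dates as
numeric days). The map value is the t-statistic of $\hat\beta_p$; two-sided
p-values use the t distribution on the residual degrees of freedom and are
BH-adjusted across the 62 parcels. Subjects with BMI below 10 or above
50 kg/m² are excluded first; when the BMI column holds standardized scores
the range filter is skipped (such scores are computed upstream — conversion
requires external growth-chart reference tables and is out of scope).
Degenerate fits never abort a map: a single-level factor is dropped with a
notice, a zero-residual-variance parcel is masked.

Minimum cohort size is `n >` number of model terms, i.e. at least one
residual degree of freedom; the three-subject toy design used in the tests
(`bmi = (-1, 0, 1)`) is deliberately admissible.

## Spin permutation nulls

The null model for map–map correspondence must preserve spatial
autocorrelation. The package uses the centroid-rotation ("spin") family:

1. Parcel centroids live on the unit sphere (`load_parcellation`
   normalizes them). 2. Rotations are drawn uniformly over SO(3) by QR
   orthonormalization of a standard-normal 3×3 matrix with sign
   correction, flipping one column when the determinant is $-1$.
3. Per rotation, the left hemisphere's centroids are rotated by $R$ and
   the right hemisphere's by the sagittally mirrored $MRM$,
   $M=\mathrm{diag}(-1,1,1)$, preserving contralateral structure.
4. Each target parcel is assigned the source parcel whose rotated
   centroid is nearest by great-circle distance. Assignments never cross
   hemispheres; a source may serve several targets (the nearest-neighbour
   variant — no bijective matching); exact ties resolve to the lowest
   source index for determinism.

The empirical two-sided p-value for a correlation is
$(1 + \#\{|r_\text{null}| \ge |r_\text{obs}|\})/(n_\text{perm}+1)$: the
+1 correction keeps p strictly positive, and the comparison allows a
$10^{-10}$ slack so that a null replicate which recomputes the observed
statistic exactly (the identity assignment) always counts as an
exceedance. Within a battery (e.g. 19 receptor maps) BH-FDR is applied
across the battery as the family. The phenotype map is the spun side by
convention; annotation maps stay fixed.

Missing parcels are masked, never imputed: correlations use jointly
non-missing parcels, and a spun map inherits missingness through the
assignment.

## PLS correspondence

The annotation matrix $X$ (parcels × features) and response map $y$ are
column z-scored. The single-response PLS extracts components by

$$w_k = \frac{X_k^\top y}{\lVert X_k^\top y\rVert},\qquad t_k = X_k w_k,
\qquad X_{k+1} = X_k - t_k \frac{X_k^\top t_k}{t_k^\top t_k},$$

the NIPALS deflation scheme with orthogonal scores; for a single response
the first direction is exactly the normalized cross-covariance vector,
which the tests use as a closed-form oracle. Scores are the deflated-matrix
projections $t_k$ (for $k=1$ they coincide with $Xw_1$). Each component is
sign-oriented so that $\mathrm{cor}(t_k, y) \ge 0$, with the flip recorded;
orientation is idempotent. The captured covariance $t_k^\top y =
\lVert X_k^\top y\rVert$ is nonincreasing in $k$. Variance explained is
defined as $100\,r^2$ with $r = \mathrm{cor}(t_k, y)$ — the definition is
validated against worked score–response pairs (e.g. a component correlating
0.654 with its response explains 42.8% of its variance).

**Component significance.** The response is spun through each ensemble
member, the model refit, and the $k$-th observed captured covariance
compared against the null distribution of $k$-th components (no axis
realignment across permutations — the simplest defensible matching). The
default tested depth is 5 components.

**Bootstrap ratios.** Parcel rows of $(X, y)$ are resampled jointly with
replacement (default 20,000 resamples at study scale; 2,000 in the desk
experiments), the model refit, and each resampled weight vector
sign-aligned to the original by a dot-product flip — without this
alignment the sign indeterminacy of PLS directions inflates the bootstrap
SD, the classic pitfall. Then $\mathrm{BR}_f = w_f / \mathrm{SD_{boot}}(w_f)$;
a zero bootstrap SD yields a signed infinite ratio, flagged rather than
fatal. Features with $|\mathrm{BR}| > 3$ (strict) are split by sign into
positive and negative lists. Resamples with fewer than three distinct
parcels are redrawn, with a bound.

## Overrepresentation

Selected gene lists are tested against user-supplied GMT collections (no
curated database ships with the package). Per set: intersect with the
reference universe ("all genes considered in the analysis"), then the
upper-tail hypergeometric probability of at least the observed overlap,
BH-FDR across sets, sorted output with a top-10 view. Positive and
negative lists run separately. Set-size filters default to [5, 2000] and
are configurable; sets empty after intersection are dropped with a notice.

## The synthetic-data generator

Every input is generated, with ground truth emitted alongside:

* **Parcellation** — golden-angle spherical lattice per hemisphere,
  restricted to one side of the sagittal plane $x=0$, jittered under the
  seed, mirrored to the other hemisphere (62 parcels, 31 per hemisphere,
  by default). The bundled DKT centroid fixture uses the real 62 DKT
  parcel names with synthetic coordinates from this generator.
* **Maps** — white Gaussian values smoothed by
  $\exp(-d^2/2\ell^2)$ over great-circle distances and re-standardized;
  default lengthscale 0.5 rad. Smoothing is restricted within hemisphere:
  cortical hemispheres are disjoint surfaces, so surface-based smoothing
  never crosses the midline. (This also matters statistically — the spin
  null mirrors rotations across hemispheres, and a generator that smooths
  through the midline creates cross-hemisphere couplings the null does not
  model.)
* **Cohorts** — BMI log-normal with mean ≈ 19 kg/m² and SD ≈ 4.2 (the
  profile of a large adolescent cohort), clipped to [10, 50] with clip
  events logged; age ≈ 10 ± 0.5 y; balanced sex; four sites with
  Normal(0, 0.02 mm) offsets; education 8–20 y; SES standard normal;
  thickness = 2.5 mm + planted per-parcel BMI effect (mm per kg/m²)
  + covariate effects + Normal(0, 0.1 mm) noise. Defaults are desk-scale
  (n = 500); consortium-scale cohorts differ mainly in power.
* **Annotation matrices** — informative columns are
  $\text{loading}_f \cdot y + \mathcal N(0, \sigma_a)$ with loadings
  either Normal(0, `loading_sd`) or explicitly supplied, $\sigma_a = 1$
  by default (0 gives noiseless rank-1 columns); null columns are
  independent autocorrelated maps; column order is shuffled; the planted
  loadings are returned as an attribute. Width defaults to 200 features —
  the 15,633-gene matrix is emulated at reduced width; nothing in the
  method depends on the full width.

All generators are pure functions of (config, seed); reruns are
byte-identical, as is the full `run_pipeline` output for a fixed
`run_config`.

## Calibration and recovery experiments

Four experiment drivers (`spin_type1_experiment`,
`pls_oracle_experiment`, `pls_recovery_experiment`,
`pls_calibration_experiment`) define the package's quantitative checks;
the problem sizes below are the package's chosen desk-scale conditions,
also used by `scripts/acceptance.R`.

* **Spin type-I error** — 500 independent autocorrelated map pairs
  (62 parcels, ℓ = 0.5), 1,000 spins each, nominal α = 0.05. The spin
  ensemble is rebuilt every 20 pairs: rejection conditional on a single
  ensemble varies noticeably, and refreshing averages that
  ensemble-conditional bias at negligible cost. The same pairs run
  through a naive unconstrained shuffle, which rejects at ≈ 0.4–0.5 —
  the inflation the spin test exists to fix.
* **Closed form** — on 50 random 31×200 instances the first-component
  weights match the normalized $X^\top y$ to cosine ≈ 1 (< 10⁻⁶
  deviation).
* **Recovery** — 20 planted instances (31 left-hemisphere parcels,
  200 features, 20 informative at fixed loadings ±1, so signal SD equals
  the unit annotation noise SD), white-noise target. Reported:
  correlation between planted and recovered loadings over the
  informative features, bootstrap-ratio sensitivity and false-positive
  rate at 2,000 resamples. Two deliberate choices here. First, the
  target is white: with a smooth target, smooth null columns correlate
  with it by chance, and the bootstrap — which measures stability of
  in-sample structure, not distance from zero — faithfully flags those
  chance correlations, which says nothing about estimator recovery.
  Second, recovery is scored on the informative subvector: across the
  full 200-vector the correlation is bounded near
  $\sqrt{SS_\text{signal}/(SS_\text{signal} + p_\text{null}/n)} \approx 0.8$
  by parcel-sampling noise on the 180 null weights regardless of signal
  strength, so the full-vector statistic measures the parcel count, not
  the estimator.
* **Component-significance calibration** — 500 replicates of independent
  autocorrelated (X, y) on the two-hemisphere 62-parcel substrate,
  1,000 spins each, ensemble refreshed every 20 replicates; component-1
  rejection at α = 0.05 lands in the low single digits of percent.

## Known limitations

* **Single-hemisphere spins on half-sphere geometry are anticonservative.**
  On a synthetic single-hemisphere parcellation occupying half a sphere,
  rotations push most centroids out of the hemisphere's own domain; the
  nearest-neighbour reassignment then degenerates (≈ 50% duplicate
  assignments) and component-significance rejection rises to ≈ 0.14 at
  α = 0.05. Real single-hemisphere spin tests do not face this: FreeSurfer
  inflates each hemisphere to its own full sphere. Calibration claims in
  this package therefore rest on the two-hemisphere substrate; left-only
  analyses (donor expression) reuse the same machinery but their spin
  p-values should be read with this caveat.
* The bootstrap ratio is a stability index: on small parcel counts it
  reliably flags chance in-sample correlations of null features
  (per-instance false-positive rates are heavy-tailed even when the
  average is a few percent).
* The generator emulates additive site offsets, Gaussian thickness noise
  and stationary isotropic autocorrelation. Real data have heavier
  tails, nonstationary smoothness, scanner-specific artefacts and
  homotopic (mirror-symmetric) correlations; passing tests here show the
  machinery is correct and calibrated under the stated model, not that
  real-data effect sizes or p-values transfer.
* Spatial-autocorrelation strength is asserted through a Moran's I
  oracle with inverse-squared-distance weights ($1/d^2$), the weighting
  under which the generator's ℓ = 0.5 maps show I ≈ 0.3 against ≈ 0 for
  white noise.
* Alternative null families (variogram-matched surrogates), bijective
  spin variants, Spearman batteries, partial correlations and
  mixed-effects site models are out of scope.
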