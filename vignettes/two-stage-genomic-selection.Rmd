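---
title: "Two-stage genomic prediction with directional dominance: models and methods"
author: "polystage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic prediction with directional dominance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystage)
```

# The problem

Plant breeding trials are grown in many environments (year–location
combinations) with different experimental designs, replication levels, and
error variances.  The standard way to combine them for genomic selection is a
two-stage analysis: Stage 1 fits a fixed-effect model per environment and
returns the genotype means (BLUEs); Stage 2 fits a genomic mixed model across
environments with the BLUEs as the response.  The catch is that a BLUE is an
*estimate*: it carries an estimation error whose variance differs between
environments (and whose covariance between genotypes within an environment is
not zero).  Ignoring this in Stage 2 mis-weights the environments.  A *fully
efficient* two-stage analysis carries the complete variance–covariance matrix
of the Stage-1 BLUEs into Stage 2 as a random effect with **known**
covariance and no free parameter, so that (under the fitted model) no
information is lost relative to a single-stage analysis.

`polystage` implements this pipeline for any even ploidy, with directional
dominance (inbreeding depression), pedigree/genomic kernel blending,
factor-analytic genotype-by-location models, multi-trait selection indices
with response restrictions, and GWAS by backsolving marker effects.

# Stage 1: genotype means per environment

For each environment, `fit_stage1()` fits
`y = genotype + covariates + error` with genotype as a fixed factor (cell
means parameterization, so BLUEs are on the observation scale).  Covariates
can be fixed or i.i.d. random; random terms are estimated by the package's
REML engine and the BLUEs are then generalized-least-squares estimates.  The
full covariance matrix of the BLUEs in each environment is retained.  A
companion model with genotype random yields the broad-sense heritability on a
plot basis, `H2 = sigma2_g / (sigma2_g + sigma2_e)`; variances of design
random effects (e.g. trials) are excluded from the denominator.

For multiple traits the residuals follow a separable model: the traits share
one design matrix, the trait covariance `Sigma_t` is estimated from OLS
residual cross-products (with a shared design, GLS equals OLS trait by
trait), and the BLUE covariance is the Kronecker product of the genotype
block of `(X'X)^-1` with `Sigma_t`.

Spatial models are deliberately out of scope; externally adjusted means and
covariances can be supplied through `as_stage1()` / `read_stage1()`.
Stage-1 design random effects are conditioned on their REML variance
estimates when the BLUE covariance is formed (standard empirical-BLUE
practice); their estimation uncertainty is not propagated.

# Stage 2: the genomic mixed model

The Stage-2 model for the BLUE of genotype *i* in environment *j* is

$$y_{ij} = E_j + g_i + (gE)_{ij} + s_{ij},$$

with fixed environment effects, a genetic effect, an i.i.d.
genotype-by-environment term that serves as the model residual, and the
Stage-1 error `s`, whose covariance is the direct sum of the per-environment
BLUE covariance blocks — fixed, not estimated.  Setting
`include_s_term = FALSE` drops the `s` term; comparing the two fits by AIC
(`compare_aic()`) measures what carrying the Stage-1 errors is worth.  The
AIC convention is `-2 logLik_REML + 2k` with `k` counting only free
(co)variance parameters, so the fixed-covariance term adds nothing and the
comparison is meaningful.

## Genetic decomposition and directional dominance

With markers, `g_i` splits into an additive value with covariance
proportional to the VanRaden-type genomic relationship

$$\mathbf G = \frac{\mathbf W \mathbf W'}{\phi \sum_k p_k q_k},$$

(`W` the column-centered dosage matrix, `phi` the ploidy) and a non-additive
value.  The non-additive part is either i.i.d. (the *genetic residual* model)
or a directional digenic dominance value.  For dosage `X` at a locus with
allele frequency `p`, the dominance coefficient is

$$Q = -2\binom{\phi}{2}p^2 + 2p(\phi-1)X - X(X-1),$$

and an individual's dominance value is `Q beta` summed over loci, where
`beta` is the digenic substitution effect.  Treating the `beta_k` as random
normal with mean `mu_beta` and variance `sigma2_beta` gives

* a genomic dominance kernel
  `D = Q Q' / (choose(phi,2) sum(4 p^2 q^2))`, whose variance component is
  the expected dominance genic variance, and
* a genomic inbreeding coefficient
  `F = -rowSums(Q) / (choose(phi,2) sum(2 p q))`, scaled so a fully
  homozygous population has mean 1 and a panmictic one mean 0.

`F` enters the model as a fixed covariate; the negative of its regression
coefficient is the heterosis parameter `b` (positive `b` = inbreeding
depression).  The covariate is centered before entering the design — this
affects only the intercepts, and the fitted coefficient is unchanged.  The
observed allele frequencies of the supplied population are used throughout;
monomorphic markers are dropped (they contribute nothing and break
per-marker scaling), and missing dosages are mean-imputed so `W` stays well
defined.

Inbreeding can also be computed from the diagonal of any additive
relationship matrix as `(K_ii - 1)/(phi - 1)`; the dominance-based `F` is the
covariate used for heterosis because it is the regression target the theory
prescribes, while the diagonal-based version is available for comparison.

## Pedigree kernel and H blending

`pedigree_A()` implements the tabular coancestry recursion for diploids and
autotetraploids (random bivalent pairing, no double reduction; for the
tetraploid, `F = F_s/6 + F_d/6 + 2 f(s,d)/3`).  This is a deliberate
simplification — higher ploidies and double reduction are out of scope.
`blend_H()` forms `H = (1-omega) G + omega A`, and `optimize_blend()` refits
Stage 2 over an `omega` grid (default 0 to 1 in steps of 0.1) and picks the
AIC minimizer.  Blending also regularizes `G`, which is singular by
construction (`G 1 = 0` because `W` is centered).

## Multiple locations and multiple traits

With `multi = "loc"`, the genetic effect becomes genotype-within-location
with separable covariance `K ⊗ Γ`, where `Γ` follows a second-order
factor-analytic model `Γ = Λ Λ' + Ψ` (`Λ` is s × 2 with the upper-right
element pinned at zero for identifiability).  With fewer than three
locations FA2 is unidentifiable and an unstructured `Γ` is substituted
silently.  `fa2_rotate()` applies a varimax rotation with a sign convention
(each column mean non-negative) and returns per-location coordinates
`Λ_i/√Γ_ii`, whose squared radius is the proportion of genetic variance
captured by the two factors — always in [0, 1].  The non-additive correlation
between locations is fixed at 1 (one dominance value per genotype): attempts
to free that correlation push it to the boundary in practice, so it is
accepted as a model limitation.  The GxE residual gets one variance per
location, and the inbreeding and fixed-marker covariates get one coefficient
per location.

With `multi = "trait"`, all trait covariance matrices (additive,
non-additive, and the per-cell GxE residual) are unstructured, parameterized
by log-Cholesky factors; environment fixed effects are trait-specific.  The
per-cell residual structure — `Sigma_gE` shared by the traits of one
genotype-environment cell, independent across cells — is a modeling choice
(the trait analog of the i.i.d. GxE residual), made because nothing stronger
is identifiable from one record per cell.  Multi-trait fits are limited to
the homogeneous GxE structure.  A multi-trait fit with a single trait
reduces exactly to the single-trait fit, which is tested.

## REML engine

All variance components are estimated by a dense-matrix average-information
(AI) REML engine written for this package, because the distinguishing
requirement — a random term with fixed, known, unscaled covariance alongside
FA2/unstructured kernels — is not expressible in the common mixed-model
packages.  Design choices:

* restricted likelihood includes the `-log|X'V^{-1}X|/2` term and the
  Gaussian constant, so values are comparable across software that uses the
  same convention;
* free parameters live on unconstrained scales (log variances, log-Cholesky
  for unstructured, loadings plus log specific variances for FA2);
* deterministic start (half the phenotypic variance split equally across
  terms), so fits are reproducible without a seed;
* AI steps with Levenberg-style damping and step halving — flat directions,
  such as a second FA2 factor near zero, make the raw AI matrix
  near-singular, and damping recovers a useful ascent direction; a
  derivative-free Nelder–Mead polish is the fallback;
* variances are clamped at `1e-8` times the phenotypic variance and flagged
  as boundary estimates ("B"), mirroring common mixed-model software;
* convergence requires both a small gradient and a stabilized likelihood;
  the engine refuses to return a point worse than its start.

The engine is validated against closed-form ANOVA estimators, an independent
brute-force likelihood implementation, lme4 on shared model classes, and
scale/translation invariance properties.

## Proportion of variance explained

`pve_summary()` quantifies each model term by its expected contribution to
the variance of the response, using the quadratic-form identity
`E[V_y] = [mean(diag K) - mean(K)] + [mean(mu^2) - mean(mu)^2]`; for
genotype-indexed effects the averages are weighted by the number of
environments per genotype, which handles unbalanced trials.  The environment
main effect is excluded (mirroring heritability).  The heterosis row is the
variance of the fitted `-bF` term; the dominance row is the kernel part; a
fixed-marker row appears when markers are fitted as covariates.  For the
multi-location model the genotype-within-location variance is split into an
additive main effect (using the mean off-diagonal of `Γ`) plus a
genotype-by-location interaction.  Rows are normalized to sum to one — this
is bookkeeping, not an orthogonal decomposition, because the model effects
are correlated through the data.

# BLUP, merit, and reliability

`blup_prep()` computes the predicted random effects and their covariance
once, by whichever of two algebraically identical routes is cheaper:
inverting the mixed-model-equation coefficient matrix when records outnumber
random effects (`var(u_hat) = var(u) - C22`), else inverting `V` directly
(`u_hat = var(u) Z'Py`, `var(u_hat) = var(u) Z'PZ var(u)`).  Ties go to the
MME route.  Because `G` is exactly singular, the MME route inverts kernels
with a `1e-8 · mean(diag)` ridge; if the coefficient matrix is still
numerically singular (e.g. both `G` and `Γ` near-singular), the code falls
back to the V route, which needs no kernel inverse.  Both routes are held to
agreement at `1e-6` in the tests.

Records can be masked by id, environment, or trait, emulating prediction of
unphenotyped candidates (marker-based selection) or unobserved environments;
masked individuals remain in the random-effect vector and are predicted
through their relationships.

`predict_merit()` evaluates the selection index
`theta = ([I γI] ⊗ c') u + ([W γF] ⊗ c') delta`: `c` is the user's weight
vector divided by the per-trait breeding-value standard deviations
`sqrt(sigma2_A + γ^2 sigma2_D)` and scaled to unit norm; `γ` weighs the
non-additive part (0 for additive value, 1 for total genotypic value,
`(phi/2 - 1)/(phi - 1)` for breeding value).  Environment effects are
excluded from merit; fixed marker and heterosis effects are included.
Reliability is `r2 = λ' var(u_hat_i) λ / λ' var(u_i) λ`, the squared
correlation with the true merit via the BLUP identity
`cov(u, u_hat) = var(u_hat)`.

The MAS/MBS relation `mas_reliability()` links the reliability of
marker-based selection (`rB2`, candidates not in the training set) to
marker-assisted selection (`rA2`, candidates phenotyped with heritability
`h2`): `rA2 = rB2 + h2 (1 - rB2)^2 / (1 - h2 rB2)`.  The acceptance suite
verifies on simulated data that masked-cohort and full-data reliabilities
from `blup_prep()` satisfy this relation to within 0.05.

# Selection response and restricted indices

`response_matrix()` builds `B`, the expected population covariance of the
predicted genetic-value vectors (computed from `var(u_hat)` and the fixed
effects through the same quadratic-form identity as the PVE, with the same
record-count weights).  The attainable responses at selection intensity `i`
form the ellipsoid `x'B^{-1}x = i^2`; `ellipse_slice()` returns 2D slices
(principal axes from the eigendecomposition of the standardized quadratic
form `Δ B^{-1} Δ`, semi-axes the inverse square roots of its eigenvalues).
The slice convention holds the non-displayed traits at a supplied response
vector (typically the optimum from `gain()`; the central slice is the
default) — the convention is a package choice, documented here because any
slice of the ellipsoid is equally valid geometry.

`gain()` maximizes the merit gain `c'x` over the ellipsoid, with optional
per-trait equality or inequality restrictions on the response (restricted
traits are dropped from the objective).  Because the objective is linear and
the feasible set convex, the optimum lies on the boundary and some subset of
the inequality constraints is active; the solver enumerates active sets of
the (few) trait constraints and solves each equality-constrained subproblem
in closed form via a null-space parameterization, then keeps the best
feasible candidate.  This is exact, deterministic, and independent of any
external optimization library; the Kempthorne–Nordskog Lagrange solution
serves as the test oracle.  Index coefficients are recovered from the
intensity-1 optimum as `c = B^{-1}x` and rescaled to unit norm; standardized
coefficients and responses (genetic-SD units) are reported whenever the
genetic SDs are available.  Singular `B` (possible in small populations) is
handled with the Moore–Penrose inverse and flagged.  Replacing an equality
restriction by the corresponding inequality can only increase the achievable
gain, which the tests assert on random response matrices.

# GWAS by backsolving

Additive substitution effects on the index scale are
`alpha_hat = (W'G^{-1} ⊗ c') a_hat / (phi Σ p q)` and digenic dominance
effects are `beta_hat = (Q'D^{-1} ⊗ c') d_hat / (choose(phi,2) Σ 4p^2q^2)`,
with `d_hat` including the fitted `-bF` part so directional dominance is
represented.  Because `G` is singular by construction, the backsolve uses the
Moore–Penrose inverse; since `a_hat` lies in the range of `G`, the GBLUP /
ridge-regression-BLUP identity `W alpha_hat = a_hat` then holds to machine
precision (a ridge would perturb it).  Standard errors come from
`var(a_hat)`; the standardized effects are asymptotically standard normal,
and the tests verify the exact algebraic equivalence of the standardized
backsolved effect with the generalized-least-squares score of the marker
under the fitted covariance.  The point estimates themselves are shrinkage
estimates and are *not* expected to equal fixed-effect regression
coefficients.  For the dominance SE, the estimation error of the fixed
heterosis coefficient is not propagated (only `var(u_hat)` is used); the
additive null calibration is unaffected.

The discovery threshold divides the genome-wide significance level by the
effective number of markers, computed per chromosome: the default sequential
rule credits marker `j` with `sqrt(1 - max_{k<j} r^2_{jk})` in map order
(duplicated markers add zero, independent markers add one); the Li–Ji
eigenvalue rule is available as an alternative.  A 200-replicate null
simulation in the acceptance suite checks that the genome-wide type-I error
stays at or below the nominal level.

# The synthetic-data generator

`sim_population()`, `sim_truth()`, and `sim_phenotypes()` reproduce the
distributional assumptions of the pipeline: binomial dosages at given allele
frequencies (panmictic baseline), optional per-individual excess
homozygosity (to create real variation in `F`), optional founder/offspring
family structure with gametes drawn without replacement (random bivalent
pairing), additive values `W alpha` and dominance values `Q beta` from
random substitution effects (`mu_beta = b / denomF` yields the prescribed
inbreeding depression `-bF`), fixed year effects, i.i.d. GxE, plot errors,
and exact Stage-1 BLUEs with heterogeneous *known* diagonal error blocks.

The default study scenario — 300 tetraploid clones, 1000 markers, 4
environments, `sigma2_A = 1`, `sigma2_D = 0.3`, `b = 5`, `sigma2_gE = 0.5`,
Stage-1 error scales in [0.5, 2] — is sized so the full acceptance suite
runs in minutes on one CPU.  The recovery scenarios use the family-structured
population (60 founders) because multi-year breeding trials are populations
of related clones, and it is precisely the spread in realized relatedness
that identifies the additive/dominance split; in a completely unrelated
panmictic sample, `G` and `D` are both near-identity and the two components
are barely separable (their sum still is).  What the generator does *not*
emulate: linkage maps and recombination-driven LD, selection over cycles,
spatial field trends, and non-diagonal Stage-1 error blocks.  Passing tests
therefore demonstrate correctness of the machinery under the stated model,
not robustness to field-data pathologies.

The family-structured simulations produce little variation in `F`
(outcrossed offspring of non-inbred founders), so the heterosis coefficient
`b` is estimated with a large standard error — the same situation reported
for real potato data, where heterosis explained only a few percent of the
variance because `sd(F)` was small.  The recovery criterion is therefore
stated in Monte-Carlo standard errors, which makes it self-scaling.

# Known limitations

* Spatial Stage-1 models, genotype calling, cross-platform dosage
  imputation, and hybrid/environmental-covariate prediction are out of
  scope by design.
* Pedigree kernels cover ploidy 2 and 4 only, without double reduction.
* Dominance is digenic only; higher-order interactions are not modeled.
* Multi-trait models assume homogeneous GxE; the heterogeneous
  (FA2-by-location) structure is single-trait only.
* The dominance SE in the GWAS omits the heterosis-coefficient uncertainty.
* Reliability and PVE condition on the Stage-2 variance estimates (empirical
  BLUP); variance-estimation uncertainty is not propagated.
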