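---
title: "Models, generators and design choices in neuroSexDiff"
author: "neuroSexDiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, generators and design choices in neuroSexDiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical models, what the synthetic-data generator emulates (and
does not), the numerical choices, and the places where the design was
genuinely open and we had to decide.

## 1. The analysis chain

The package studies one causal hypothesis on synthetic adolescent
cohorts: polygenic risk for internalizing disorders acts on the sexual
differentiation of functional brain connectivity in late childhood (T1),
which predicts pubertal/physiological maturation in early adolescence
(T2), which in turn predicts the change in internalizing symptoms from
T2 to T3. The implementation decomposes into:

1. **Reference template.** On an adult reference cohort, every Fisher-z
   connectivity edge is regressed on biological sex (+1 male, −1 female)
   and a covariate set (age, income, education, employment, race,
   handedness, six psychopathology scores, mean framewise displacement,
   two cognition scores). The template entry is the *t*-statistic of the
   sex coefficient; the sign convention makes masculine-typical coupling
   positive. The template is exactly antisymmetric under flipping the
   sex code — a property asserted in the tests.

2. **Regional differentiation profiles.** For each adolescent and each
   region, the Spearman correlation between the subject's regional
   connectivity profile (their row of the FC matrix) and the template's
   corresponding row, off-diagonal entries only. The diagonal (a
   self-correlation, undefined after the Fisher transform) is excluded;
   ties take average ranks. Rank correlations are invariant to strictly
   monotone transforms of either row, which the tests exercise.

3. **Biological age.** A Gompertz proportional-hazards model
   $h(t) = \exp(b_0 + b_{age} a + \sum_k b_k x_k)\, e^{\gamma t}$ is
   fitted by maximum likelihood (analytic gradient, `nlminb` start, BFGS
   polish) on a mortality reference cohort with administrative censoring
   at horizon $\tau$. An age-only submodel is fitted on the same cohort;
   predicted cumulative risk from the full model is inverted through the
   age-only submodel to a biological age ("the age at which that risk
   would be normal in the reference group"). The inversion works on the
   log cumulative hazard, which is algebraically identical to inverting
   the risk but does not saturate in double precision for extreme
   subjects. Age/sex-adjusted acceleration is the OLS residual of
   biological age on chronological age and sex.

4. **Pubertal indices.** Hormonal indices are residualized within sex
   for saliva covariates (plus menstrual covariates in girls), z-scored
   within sex, combined (girls' adrenarche = mean of z-DHEA and
   z-testosterone; boys' = z-DHEA; gonadarche = z-estradiol in girls,
   z-testosterone in boys), then re-standardized within sex before
   pooling. The raw definitional combination is available via
   `restandardize = FALSE`. Self-report indices are means of the stated
   item sets (skin/body-hair for adrenarche; growth spurt plus
   breast/menarche or voice/facial hair for gonadarche), with missing
   items dropped from the mean.

5. **Cross-validated CCA and PLS.** Both engines standardize internally
   and are validated against independent oracles (the generalized
   eigenproblem of $\Sigma_{xx}^{-1}\Sigma_{xy}\Sigma_{yy}^{-1}\Sigma_{yx}$
   for CCA; a plain SVD of the cross-correlation for PLS). Ten-fold
   cross-validation fits confound residualization, standardization and
   weights on the training folds only and applies them to the left-out
   fold; fold weight signs are aligned to the first fold (weight-vector
   dot product), since the SVD sign is arbitrary and concatenation is
   meaningless without an alignment. r_CV is the correlation of the
   concatenated test-fold variate pair.

6. **Resampling inference.** CCA permutation p-values re-run the entire
   cross-validation per permutation with the Y-set rows permuted
   (conservative; avoids any optimism from reusing trained weights).
   The four-step cross-validated PLS test permutes the behavior set with
   one subject ordering shared across brain conditions — preserving the
   T1/T2 interdependence of the brain scores — and *re-runs the
   cross-validated weighting per permutation*. We verified empirically
   that permuting only the concatenated LV scores is anticonservative
   (rejection ≈ 0.25 at α = 0.05 under a global null): the fold-wise
   training saliences overlap across folds and couple the two score
   sets. Concatenated predictions are additionally centered within fold,
   removing fold-level mean shifts shared through the common split.
   Bootstrap intervals are percentile intervals from case resampling;
   degenerate resamples (a constant variate) are redrawn and counted.

7. **Serial mediation.** Model-81 topology: M1 ~ X + C; M2 ~ X + M1 + C;
   M3 ~ X + M1 + C; Y ~ X + M1 + M2 + M3 + C, all by OLS with HC3
   standard errors (the heteroscedasticity-consistent family member with
   the best small-sample behavior). Five specific indirect effects are
   products of path coefficients; on fitted coefficients
   total = direct + Σ indirect holds exactly, and the tests assert it at
   1e-10. Confidence intervals are percentile bootstrap over case
   resampling with all four equations refitted jointly per resample.
   All analysis variables are z-scored before fitting (standardized
   effect semantics); the pre-adjustment for T1 pubertal measures and
   confounds is done through the covariate set.

8. **Spin tests.** Hemisphere-paired spatially constrained permutations:
   a Haar-uniform rotation for the left hemisphere, its x-mirrored
   counterpart for the right, greedy closest-pairs-first one-to-one
   matching of rotated to original centroids. Every row is a
   hemisphere-preserving bijection, so spun maps keep their value
   multiset exactly. Two-sided p-values use the +1 convention.

## 2. What the synthetic generator emulates

`simConfig()` + the `generate*()` functions produce every input the
pipeline consumes, with planted ground truth:

- **Parcel geometry.** Each hemisphere's parcels are laid out with a
  Fibonacci lattice over that hemisphere's *own full unit sphere* — the
  analogue of the per-hemisphere spherical registration surface on which
  spin rotations are actually defined. We first tried confining each
  hemisphere to a half-sphere; that representation is not closed under
  rotation (boundary parcels rotate out of the covered cap and the
  greedy matching must send them far away), and no half-to-full-sphere
  reparametrization can fix it (any such map collapses the boundary
  circle). With full per-hemisphere spheres, spun smooth maps retain
  their Moran's I within ~6% at 300 parcels (the resolution the tests
  use for that property); at 100 parcels the greedy matching's
  discretization costs ~15%.

- **Planted sex effect.** The male-minus-female mean difference on edge
  (i, j) is `sexEffectScale * (ar_i + ar_j + 2λ ar_i ar_j)` with `ar`
  the standardized ranks of the planted S-A axis (spatially smooth by
  default: the rank of the z coordinate) and `λ = axisInteraction`.
  The interaction term matters: a purely additive effect gives every
  regional profile identical signal-to-noise along the axis (row-wise
  rank correlations are location/scale invariant), so regional
  differentiation would be provably flat along the axis and no regional
  analysis could recover the gradient. λ defaults to 0.28, the largest
  value that keeps the per-row template slope positive at every region
  (the slope factor is 1 + 2λ·ar, and standardized ranks are bounded by
  √3), so the loading map stays monotone along the axis rather than
  folding.

- **Causal chain.** Unit-variance latents with configurable path
  coefficients: standardized anxiety PRS → T1 brain score b₁ → T2
  physiology composite f₂ → symptom-change score, plus a configurable
  direct effect. Because all latents have unit variance, the implied
  PRS-symptom correlation is the product of the three path coefficients
  plus the direct effect — a closed form the tests check at n = 2000.
  The T2 brain score is an AR-style carry-over of b₁ (stability 0.6)
  with no direct PRS path, giving the mediation's alternate arms
  something real but non-causal to adjust for. The regional expression
  adds `brainLoadScale * b_t * ar_i` to region i's differentiation gain;
  0.08 per unit latent was fixed by an a-priori power analysis so the
  chain is detectable at the default sizes (500 adolescents, 100
  parcels, 400 reference adults) while single edges stay noisy.

- **Phenotypes.** Hormone distributions match the reported assay
  summaries (means/SDs/ranges by sex and wave, pg/mL); estradiol exists
  only for girls; PDS items are 1–4 integers with separate T1 and T2
  item sets (T1 reflects an independent early-maturation latent — using
  one shared set would let the T1 pubertal adjustment partial out the
  planted T2 physiology signal); the 8 blood-chemistry biomarkers sit in
  physiological ranges and load on f₂ with signs aligned to their
  mortality coefficients; BMI, financial deprivation and medical-visit
  counts load on f₂; nine symptom scales exist at T2 and T3 with the
  internalizing triplet carrying the planted change signal. Genotypes
  are independent SNPs (7/3/12 per disorder) with MAF in (0.05, 0.5);
  risk scores are filtered weighted dosage sums. No linkage
  disequilibrium, no family structure, no realistic BOLD
  autocorrelation — so passing tests demonstrate the statistical
  machinery, not robustness to those real-data features.

- **Mortality reference.** Event times are drawn exactly from the
  Gompertz hazard via inverse-CDF sampling, censored at the horizon.
  Defaults (b₀ = −8.15, b_age = 0.11/yr, standardized biomarker effects
  0.6–0.75 in magnitude, γ = 0.2/yr, τ = 15 yr, ages 20–40, n = 5000)
  were chosen by a-priori conditioning analysis so that (i) every
  coefficient is recoverable within 10% relative error at n = 5000 —
  γ is the binding constraint and needs a steep hazard and a long
  horizon — and (ii) the mean biological age stays within a year of the
  mean chronological age. The two requirements trade off through the
  event fraction: with very many events, frailty from the strong
  biomarker effects flattens the fitted age-only submodel and biases
  the anchoring upward; with few events γ is poorly identified. The
  default sits near the crossing point (~55% events).

## 3. Numerical choices

- CCA uses Cholesky whitening of the two correlation blocks plus an SVD
  of the whitened cross-correlation; a pivoted-QR route takes over when
  either block is numerically rank-deficient (pseudo-inverse semantics,
  with a warning when n ≤ p_x + p_y).
- Correlations are clipped to |r| ≤ 1 − 1e-7 before the Fisher
  transform; the FC diagonal is masked (`NA`), never imputed.
- The respiratory band-stop (0.31–0.43 Hz) is an order-4 Butterworth
  applied forward-backward (zero phase); the contracts (≥ 90% in-band
  attenuation, ≤ 5% out-of-band ripple, DC passthrough) are checked with
  an FFT oracle.
- Motion exclusion uses strict inequalities for the FD thresholds
  (mean FD < 0.20 mm; frames counted below 0.20 mm strictly; maximum
  excursion < 5 mm) and "at least 80%" for the frame fraction.
- Zero-variance covariate columns (for example an adoption flag that
  never fires in a draw) are dropped from every design matrix: they
  carry no adjustment information and would make solves singular.
- `standardizedContributions()` partials controls out by Frisch–Waugh;
  a predictor left with no unique variance is reported as a zero
  contribution with a warning rather than an unstable coefficient.
- Reporting orientation in the pipeline: the psychopathology variate is
  flipped (together with its partner) to correlate positively with the
  mean internalizing change score. Variate signs are otherwise
  arbitrary, and the serial indirect effect's sign equals the outcome
  variate's orientation, so a deterministic convention keeps reported
  effects comparable across runs.

## 4. Problem sizes used by the tests

The test suite validates oracle equivalence on hundreds of small random
instances; calibration of the three permutation tests with 200 null
replicates at 400–500 permutations each; planted-chain recovery at the
default study scale (100 mediation replicates at reduced bootstrap
resampling, 500 draws); and mortality-model recovery at n = 5000. The
pipeline's own defaults (1000 permutations / 1000 bootstrap draws) are
desk-scale; config flags raise them to the study scale (100,000 / 50,000)
when wanted.

## 5. Known limitations

- The generator's linear-Gaussian chain cannot probe nonlinear or
  interaction-driven mediation; the mediation engine is OLS-based by
  design (as is the original macro it mirrors).
- Greedy closest-pairs-first matching is order-dependent near ties; it
  is documented behavior, not an optimal-transport assignment.
- Cross-hemisphere centroid distances mix the two per-hemisphere
  registration spheres and should not be over-interpreted; the QC-FC
  distance-dependence diagnostic is driven by the within-hemisphere
  pairs.
- The biological-age model is a two-stage Gompertz construction; it does
  not model competing risks, and the intrinsic-cause filtering of the
  reference cohort is a generator flag, not a model feature.
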