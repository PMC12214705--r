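#' @import methods
NULL

#' Adult reference template of sex-linked functional connectivity
#'
#' Symmetric matrix of per-edge t-statistics for the biological-sex
#' coefficient (male coded +1, female -1) from edge-wise ordinary least
#' squares on an adult reference cohort, adjusted for the configured
#' covariates. Positive entries mark edges with stronger coupling in males.
#' The diagonal (self-coupling) is undefined and stored as \code{NA}.
#'
#' @slot tstat numeric R x R symmetric matrix of sex t-statistics, \code{NA}
#'   diagonal.
#' @slot dof residual degrees of freedom of the edge-wise regressions.
#' @slot covariates character vector of adjustment covariate names.
#' @exportClass SexDiffTemplate
setClass("SexDiffTemplate",
  representation(tstat = "matrix", dof = "numeric", covariates = "character"))

setValidity("SexDiffTemplate", function(object) {
  m <- object@tstat
  if (nrow(m) != ncol(m)) return("t-statistic matrix must be square")
  off <- m[lower.tri(m)]
  if (any(!is.finite(off))) return("non-finite off-diagonal t-statistics")
  if (max(abs(m[lower.tri(m)] - t(m)[lower.tri(m)])) > 1e-8)
    return("t-statistic matrix must be symmetric")
  if (object@dof < 1) return("degrees of freedom must be positive")
  TRUE
})

#' Gompertz proportional-hazards mortality model
#'
#' Exponential-growth mortality model
#' \eqn{h(t) = \exp(b_0 + b_{age} a + \sum_k b_k x_k)\, e^{\gamma t}}
#' with administrative censoring horizon \eqn{\tau}, plus an age-only
#' submodel used to invert predicted mortality risk to a biological age.
#'
#' @slot intercept log-hazard intercept \eqn{b_0}.
#' @slot ageCoef chronological-age coefficient (per year); the age-only
#'   submodel's coefficient must be positive for invertibility.
#' @slot biomarkerCoef named biomarker coefficients.
#' @slot gamma Gompertz shape (per year), positive.
#' @slot horizon prediction horizon \eqn{\tau} in years.
#' @slot ageOnly list with elements \code{intercept}, \code{ageCoef},
#'   \code{gamma} for the age-only submodel.
#' @slot logLik maximized log-likelihood of the full model.
#' @slot n number of subjects; \code{nEvents} observed deaths.
#' @slot nEvents number of observed deaths.
#' @exportClass GompertzMortalityModel
setClass("GompertzMortalityModel",
  representation(intercept = "numeric", ageCoef = "numeric",
                 biomarkerCoef = "numeric", gamma = "numeric",
                 horizon = "numeric", ageOnly = "list", logLik = "numeric",
                 n = "numeric", nEvents = "numeric"))

setValidity("GompertzMortalityModel", function(object) {
  if (object@gamma <= 0) return("gamma must be positive")
  if (object@horizon <= 0) return("horizon must be positive")
  if (object@ageOnly$ageCoef <= 0)
    return("age-only submodel age coefficient must be positive (invertibility)")
  TRUE
})

#' Canonical correlation model
#'
#' Weights and canonical correlations from a (training-set) canonical
#' correlation analysis; columns of both sets are standardized internally
#' and the training means/SDs are retained so the model can be projected
#' onto new data without refitting.
#'
#' @slot xWeights,yWeights weight matrices (variables x variates).
#' @slot cors canonical correlations, non-increasing, in [0, 1].
#' @slot xCenter,xScale,yCenter,yScale training-set standardization.
#' @exportClass CcaModel
setClass("CcaModel",
  representation(xWeights = "matrix", yWeights = "matrix", cors = "numeric",
                 xCenter = "numeric", xScale = "numeric",
                 yCenter = "numeric", yScale = "numeric"))

setValidity("CcaModel", function(object) {
  r <- object@cors
  if (any(r < -1e-8 | r > 1 + 1e-8)) return("canonical correlations outside [0,1]")
  if (is.unsorted(rev(r), strictly = FALSE) && any(diff(r) > 1e-8))
    return("canonical correlations must be non-increasing")
  TRUE
})

#' Cross-validated canonical correlation result
#'
#' Test-fold predicted variates concatenated across folds, their correlation
#' (r_CV), permutation significance and per-variable loading estimates with
#' percentile bootstrap intervals.
#'
#' @slot scoresX,scoresY concatenated test-fold predicted variates (first
#'   variate pair), in original subject order.
#' @slot rCV correlation of the predicted variate pair.
#' @slot permP permutation p-value (NA until computed).
#' @slot loadings data.frame: variable, set, estimate, lo, hi.
#' @slot folds integer fold assignment per subject.
#' @slot seed integer seed used for fold assignment.
#' @slot residualX,residualY confound-residualized observed data (used for
#'   loadings and bootstrap).
#' @exportClass CvCcaResult
setClass("CvCcaResult",
  representation(scoresX = "numeric", scoresY = "numeric", rCV = "numeric",
                 permP = "numeric", loadings = "data.frame",
                 folds = "integer", seed = "integer",
                 residualX = "matrix", residualY = "matrix"))

setValidity("CvCcaResult", function(object) {
  if (length(object@folds) != length(object@scoresX))
    return("fold assignment length must match scores")
  if (nrow(object@loadings) &&
      any(object@loadings$lo > object@loadings$hi + 1e-12))
    return("loading CI endpoints must be ordered")
  TRUE
})

#' Partial least squares correlation model
#'
#' Singular value decomposition of the correlation between a behavior set
#' and a brain set whose conditions (for example two timepoints) are stacked
#' as blocks of columns. Salience vectors are unit norm per latent variable;
#' covariance explained is the squared singular value over their sum.
#'
#' @slot brainSaliences (R * conditions) x L salience matrix.
#' @slot behaviorSaliences B x L salience matrix.
#' @slot singularValues non-increasing singular values.
#' @slot covExplained fractions summing to one.
#' @slot conditions number of stacked brain conditions.
#' @slot brainCenter,brainScale,behaviorCenter,behaviorScale training
#'   standardization parameters.
#' @exportClass PlsModel
setClass("PlsModel",
  representation(brainSaliences = "matrix", behaviorSaliences = "matrix",
                 singularValues = "numeric", covExplained = "numeric",
                 conditions = "integer",
                 brainCenter = "numeric", brainScale = "numeric",
                 behaviorCenter = "numeric", behaviorScale = "numeric"))

setValidity("PlsModel", function(object) {
  if (abs(sum(object@covExplained) - 1) > 1e-8)
    return("covariance-explained fractions must sum to 1")
  nrm <- sqrt(colSums(object@brainSaliences^2))
  if (any(abs(nrm - 1) > 1e-6)) return("brain saliences must be unit norm")
  TRUE
})

#' Cross-validated partial least squares result
#'
#' Test-fold brain and behavior latent-variable scores, per-condition
#' correlations of the behavior variates with the predicted brain latent
#' variable, permutation significance via a shared within-condition subject
#' permutation, and percentile bootstrap intervals.
#'
#' @slot brainScores n x conditions predicted brain LV scores.
#' @slot behaviorScores n predicted behavior LV scores.
#' @slot corByCondition named matrix of correlations (behavior variable x
#'   condition).
#' @slot permP permutation p-value of the cross-validated singular value.
#' @slot cis data.frame of bootstrap CIs for the per-condition correlations.
#' @slot loadingMap R x conditions per-parcel correlations with the
#'   predicted brain LV.
#' @slot folds integer fold assignment; \code{seed} the fold seed.
#' @slot seed integer seed.
#' @exportClass CvPlsResult
setClass("CvPlsResult",
  representation(brainScores = "matrix", behaviorScores = "numeric",
                 corByCondition = "matrix", permP = "numeric",
                 cis = "data.frame", loadingMap = "matrix",
                 folds = "integer", seed = "integer"))

#' Serial-parallel path model (model-81 topology)
#'
#' Four ordinary least squares equations: \code{M1 ~ X + C},
#' \code{M2 ~ X + M1 + C}, \code{M3 ~ X + M1 + C} and
#' \code{Y ~ X + M1 + M2 + M3 + C}, with heteroscedasticity-consistent (HC3)
#' standard errors. One first-stage mediator (M1) feeds two parallel
#' second-stage mediators (M2, M3) between exposure X and outcome Y.
#'
#' @slot coefTable data.frame with equation, term, estimate, HC3 se, t,
#'   two-tailed p and residual dof.
#' @slot paths named numeric vector of the path coefficients used for
#'   indirect effects (a1, a2, a3, d21, d31, b1, b2, b3, cPrime, total).
#' @slot n number of complete cases; \code{standardized} whether analysis
#'   variables were z-scored before fitting.
#' @slot standardized logical.
#' @exportClass PathModel81
setClass("PathModel81",
  representation(coefTable = "data.frame", paths = "numeric", n = "numeric",
                 standardized = "logical"))

#' Indirect, direct and total effects of a model-81 fit
#'
#' Five specific indirect effects (X->M1->Y, X->M2->Y, X->M3->Y,
#' X->M1->M2->Y, X->M1->M3->Y), their sum, the direct and total effects,
#' with optional percentile-bootstrap confidence intervals. On fitted
#' coefficients the decomposition total = direct + sum(indirect) is exact.
#'
#' @slot effects named numeric vector of effects.
#' @slot ci matrix of CI bounds (rows = effects) or 0-row matrix.
#' @slot level CI level; \code{nBoot} bootstrap draws (0 if analytic only).
#' @slot nBoot number of bootstrap samples used.
#' @exportClass IndirectEffects
setClass("IndirectEffects",
  representation(effects = "numeric", ci = "matrix", level = "numeric",
                 nBoot = "numeric"))

setValidity("IndirectEffects", function(object) {
  e <- object@effects
  need <- c("indirect_m1", "indirect_m2", "indirect_m3", "serial_m1_m2",
            "serial_m1_m3", "total_indirect", "direct", "total")
  if (!all(need %in% names(e))) return("missing effect entries")
  if (abs(e["total"] - e["direct"] - e["total_indirect"]) > 1e-8)
    return("total != direct + total indirect")
  TRUE
})

#' Hemisphere-paired spatially constrained permutations
#'
#' A set of permutations of parcel indices generated by random rotations of
#' the parcel centroids on the sphere (the right hemisphere receives the
#' mirrored rotation), each rotation resolved to a one-to-one assignment by
#' greedy closest-pairs-first matching. Every row is a bijection of 1..R
#' that maps left parcels to left parcels and right parcels to right.
#'
#' @slot perms nPerm x R integer matrix of permutation indices.
#' @slot hemisphere character vector ("L"/"R") per parcel.
#' @slot seed integer seed used to draw the rotations.
#' @exportClass SpinNullSet
setClass("SpinNullSet",
  representation(perms = "matrix", hemisphere = "character", seed = "integer"))

setValidity("SpinNullSet", function(object) {
  R <- ncol(object@perms)
  if (length(object@hemisphere) != R) return("hemisphere labels must match R")
  ok <- apply(object@perms, 1, function(p) {
    all(sort(p) == seq_len(R)) && all(object@hemisphere[p] == object@hemisphere)
  })
  if (!all(ok)) return("rows must be hemisphere-preserving bijections")
  TRUE
})
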