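#' Accessors for neuroSexDiff result objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object a neuroSexDiff S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tstatMatrix", function(object) standardGeneric("tstatMatrix"))

#' @rdname accessors
#' @export
setGeneric("templateDof", function(object) standardGeneric("templateDof"))

#' @rdname accessors
#' @export
setGeneric("canonicalCorrelations",
           function(object) standardGeneric("canonicalCorrelations"))

#' @rdname accessors
#' @export
setGeneric("rCV", function(object) standardGeneric("rCV"))

#' @rdname accessors
#' @export
setGeneric("permutationP", function(object) standardGeneric("permutationP"))

#' @rdname accessors
#' @export
setGeneric("loadingTable", function(object) standardGeneric("loadingTable"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("covarianceExplained",
           function(object) standardGeneric("covarianceExplained"))

#' @rdname accessors
#' @export
setGeneric("loadingMap", function(object) standardGeneric("loadingMap"))

#' @rdname accessors
#' @export
setGeneric("pathCoefficients",
           function(object) standardGeneric("pathCoefficients"))

#' @rdname accessors
#' @export
setGeneric("effectTable", function(object) standardGeneric("effectTable"))

#' @rdname accessors
#' @export
setGeneric("spinPermutations",
           function(object) standardGeneric("spinPermutations"))

setMethod("tstatMatrix", "SexDiffTemplate", function(object) object@tstat)
setMethod("templateDof", "SexDiffTemplate", function(object) object@dof)
setMethod("canonicalCorrelations", "CcaModel", function(object) object@cors)
setMethod("rCV", "CvCcaResult", function(object) object@rCV)
setMethod("permutationP", "CvCcaResult", function(object) object@permP)
setMethod("permutationP", "CvPlsResult", function(object) object@permP)
setMethod("loadingTable", "CvCcaResult", function(object) object@loadings)
setMethod("singularValues", "PlsModel", function(object) object@singularValues)
setMethod("covarianceExplained", "PlsModel",
          function(object) object@covExplained)
setMethod("loadingMap", "CvPlsResult", function(object) object@loadingMap)
setMethod("pathCoefficients", "PathModel81", function(object) object@paths)
setMethod("effectTable", "IndirectEffects", function(object) {
  data.frame(effect = names(object@effects), estimate = unname(object@effects),
             lo = if (nrow(object@ci)) object@ci[names(object@effects), 1] else NA_real_,
             hi = if (nrow(object@ci)) object@ci[names(object@effects), 2] else NA_real_,
             row.names = NULL)
})
setMethod("spinPermutations", "SpinNullSet", function(object) object@perms)

setMethod("show", "SexDiffTemplate", function(object) {
  cat("SexDiffTemplate:", nrow(object@tstat), "parcels,",
      "residual dof", object@dof, "\n")
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  off <- object@tstat[lower.tri(object@tstat)]
  cat(sprintf("  |t| range %.2f..%.2f, masculine (t>0) edges %.1f%%\n",
              min(abs(off)), max(abs(off)), 100 * mean(off > 0)))
})

setMethod("show", "GompertzMortalityModel", function(object) {
  cat("GompertzMortalityModel:", object@n, "subjects,",
      object@nEvents, "events\n")
  cat(sprintf("  b0 %.3f, b_age %.4f /yr, gamma %.4f /yr, horizon %g yr\n",
              object@intercept, object@ageCoef, object@gamma, object@horizon))
  cat(sprintf("  age-only submodel: b0' %.3f, b_age' %.4f, gamma' %.4f\n",
              object@ageOnly$intercept, object@ageOnly$ageCoef,
              object@ageOnly$gamma))
  cat(sprintf("  logLik %.3f\n", object@logLik))
})

setMethod("show", "CcaModel", function(object) {
  cat("CcaModel:", ncol(object@xWeights), "variate pair(s);",
      "canonical correlations:",
      paste(sprintf("%.3f", object@cors), collapse = ", "), "\n")
})

setMethod("show", "CvCcaResult", function(object) {
  cat(sprintf("CvCcaResult: r_CV = %.3f over %d subjects (%d folds)\n",
              object@rCV, length(object@scoresX),
              length(unique(object@folds))))
  if (!is.na(object@permP))
    cat(sprintf("  permutation p = %.4g\n", object@permP))
  if (nrow(object@loadings))
    cat("  loadings for", nrow(object@loadings), "variables (99% CIs)\n")
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel:", length(object@singularValues), "latent variable(s),",
      object@conditions, "condition(s)\n")
  cat("  covariance explained:",
      paste(sprintf("%.1f%%", 100 * object@covExplained), collapse = ", "),
      "\n")
})

setMethod("show", "CvPlsResult", function(object) {
  cat("CvPlsResult over", length(object@behaviorScores), "subjects\n")
  for (j in seq_len(ncol(object@corByCondition)))
    cat(sprintf("  condition %d: r = %s\n", j,
                paste(sprintf("%.3f", object@corByCondition[, j]),
                      collapse = ", ")))
  if (!is.na(object@permP))
    cat(sprintf("  permutation p = %.4g\n", object@permP))
})

setMethod("show", "PathModel81", function(object) {
  cat("PathModel81 (serial-parallel mediation), n =", object@n,
      if (object@standardized) "(standardized)" else "", "\n")
  print(object@coefTable, digits = 3)
})

setMethod("show", "IndirectEffects", function(object) {
  print(effectTable(object), digits = 3)
})

setMethod("show", "SpinNullSet", function(object) {
  cat("SpinNullSet:", nrow(object@perms), "hemisphere-paired spins of",
      ncol(object@perms), "parcels\n")
})
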