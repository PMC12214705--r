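# Negative log-likelihood and gradient of the Gompertz proportional-hazards
# model with administrative censoring. Parameters: coefficients on the
# design columns (including intercept) and log(gamma).
gompertzNll <- function(par, X, time, died) {
  p <- ncol(X)
  lp <- drop(X %*% par[seq_len(p)])
  g <- exp(par[p + 1])
  A <- (exp(g * time) - 1) / g
  -sum(died * (lp + g * time) - exp(lp) * A)
}

gompertzGrad <- function(par, X, time, died) {
  p <- ncol(X)
  lp <- drop(X %*% par[seq_len(p)])
  g <- exp(par[p + 1])
  egt <- exp(g * time)
  A <- (egt - 1) / g
  w <- died - exp(lp) * A
  dA <- (time * egt * g - (egt - 1)) / g^2
  -c(drop(crossprod(X, w)), g * sum(died * time - exp(lp) * dA))
}

#' Fit the Gompertz mortality model
#'
#' Maximum-likelihood fit of the exponential-growth mortality model
#' \eqn{h(t) = \exp(b_0 + b_{age} a + \sum_k b_k x_k) e^{\gamma t}} on a
#' reference cohort with administrative censoring, together with the
#' age-only submodel that is later inverted to a biological-age
#' prediction.
#'
#' @param cohort data.frame with the biomarker columns,
#'   \code{chronological_age}, \code{follow_up} and logical \code{died}.
#' @param biomarkers character vector of the biomarker column names.
#' @param horizon prediction horizon \eqn{\tau} in years (default: the
#'   maximum follow-up).
#' @return a \linkS4class{GompertzMortalityModel}.
#' @export
fitMortalityModel <- function(cohort, biomarkers = biomarkerReference()$name,
                              horizon = NULL) {
  if (!any(cohort$died)) stop("no events: cannot fit a mortality model")
  if (sum(cohort$died) < 30) stop("at least 30 events required")
  if (anyNA(cohort[biomarkers])) stop("missing biomarker values")
  horizon <- horizon %||% max(cohort$follow_up)
  time <- cohort$follow_up
  died <- cohort$died
  fitOne <- function(X) {
    crude <- log(sum(died) / sum(time))
    init <- c(crude, rep(0, ncol(X) - 1), log(0.05))
    fit <- nlminb(init, gompertzNll, gompertzGrad, X = X, time = time,
                  died = died, control = list(iter.max = 2000))
    fit2 <- optim(fit$par, gompertzNll, gompertzGrad, X = X, time = time,
                  died = died, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-12))
    gn <- sqrt(sum(gompertzGrad(fit2$par, X, time, died)^2))
    if (gn > 1e-3 * max(1, abs(fit2$value)))
      stop(sprintf("mortality model did not converge (gradient norm %.3g)",
                   gn))
    fit2
  }
  Xfull <- cbind(1, age = cohort$chronological_age,
                 as.matrix(cohort[biomarkers]))
  full <- fitOne(Xfull)
  Xage <- cbind(1, age = cohort$chronological_age)
  ageFit <- fitOne(Xage)
  p <- ncol(Xfull)
  bio <- full$par[3:p]
  names(bio) <- biomarkers
  new("GompertzMortalityModel",
      intercept = full$par[1], ageCoef = full$par[2], biomarkerCoef = bio,
      gamma = exp(full$par[p + 1]), horizon = horizon,
      ageOnly = list(intercept = ageFit$par[1], ageCoef = ageFit$par[2],
                     gamma = exp(ageFit$par[3])),
      logLik = -full$value, n = nrow(cohort), nEvents = sum(died))
}

#' Predicted mortality risk over the model horizon
#'
#' Closed-form Gompertz cumulative risk
#' \eqn{M = 1 - \exp(-\exp(b_0 + b_{age} a + \sum_k b_k x_k)
#' (e^{\gamma \tau} - 1)/\gamma)}.
#'
#' @param model a \linkS4class{GompertzMortalityModel}.
#' @param age chronological age(s) in years.
#' @param biomarkers matrix or data.frame of biomarker values (columns in
#'   model order).
#' @return risk in (0, 1) per subject.
#' @export
predictMortality <- function(model, age, biomarkers) {
  B <- as.matrix(biomarkers)[, names(model@biomarkerCoef), drop = FALSE]
  lp <- model@intercept + model@ageCoef * age +
    drop(B %*% model@biomarkerCoef)
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  g <- model@gamma
  1 - exp(-exp(lp) * (exp(g * model@horizon) - 1) / g)
}

#' Invert mortality risk to a biological age
#'
#' Solves the age-only submodel \eqn{M'(a) = \mathrm{risk}} for the
#' chronological age at which that mortality risk would be normal in the
#' reference cohort:
#' \eqn{a = (\log(-\gamma' \log(1 - M)/(e^{\gamma' \tau} - 1)) -
#' b_0')/b_{age}'}.
#'
#' @param model a \linkS4class{GompertzMortalityModel}.
#' @param risk mortality risk(s) in (0, 1).
#' @return biological age in years.
#' @export
invertToPhenoAge <- function(model, risk) {
  if (any(risk <= 0 | risk >= 1)) stop("risk must lie in (0, 1)")
  ao <- model@ageOnly
  g <- ao$gamma
  (log(-g * log(1 - risk) / (exp(g * model@horizon) - 1)) - ao$intercept) /
    ao$ageCoef
}

#' Biological age for a set of subjects
#'
#' Predicted mortality risk from the full model, inverted through the
#' age-only submodel. The inversion works on the log cumulative hazard
#' (algebraically identical to inverting the risk, but immune to the
#' floating-point saturation of risks indistinguishable from 1), so
#' subjects in the extreme tails still receive finite biological ages.
#'
#' @inheritParams predictMortality
#' @return biological age in years per subject.
#' @export
phenoAge <- function(model, age, biomarkers) {
  B <- as.matrix(biomarkers)[, names(model@biomarkerCoef), drop = FALSE]
  lp <- model@intercept + model@ageCoef * age +
    drop(B %*% model@biomarkerCoef)
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  g <- model@gamma
  logH <- lp + log((exp(g * model@horizon) - 1) / g)
  ao <- model@ageOnly
  gp <- ao$gamma
  (logH + log(gp) - log(exp(gp * model@horizon) - 1) - ao$intercept) /
    ao$ageCoef
}

#' Age- and sex-adjusted biological-age acceleration
#'
#' Ordinary least squares residual of biological age on chronological age
#' and sex within the supplied sample; residuals have zero mean and zero
#' correlation with age and sex by construction.
#'
#' @param phenoage biological ages (years).
#' @param age chronological ages (years).
#' @param sex sex codes.
#' @return residual years per subject.
#' @export
ageAcceleration <- function(phenoage, age, sex) {
  if (length(phenoage) < 10) stop("at least 10 subjects required")
  if (var(age) <= 0) stop("constant age rejected")
  res <- residualizeFitApply(phenoage, data.frame(age = age, sex = sex))
  unname(drop(res))
}
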