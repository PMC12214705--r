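# Build the four model-81 design matrices once; rows are complete cases.
med81Designs <- function(dat, Z) {
  list(
    m1 = cbind(1, x = dat$X, Z),
    m2 = cbind(1, x = dat$X, m1 = dat$M1, Z),
    m3 = cbind(1, x = dat$X, m1 = dat$M1, Z),
    y  = cbind(1, x = dat$X, m1 = dat$M1, m2 = dat$M2, m3 = dat$M3, Z),
    tot = cbind(1, x = dat$X, Z))
}

# Path coefficients from three multi-response QR solves: M2 and M3 share a
# design, and the total-effect equation shares the M1 design.
med81Paths <- function(dat, Z) {
  one <- rep(1, length(dat$X))
  A <- cbind(one, dat$X, Z)                      # M1 ~ X + C; Y ~ X + C
  cA <- qr.coef(qr(A), cbind(dat$M1, dat$Y))
  B <- cbind(one, dat$X, dat$M1, Z)              # M2/M3 ~ X + M1 + C
  cB <- qr.coef(qr(B), cbind(dat$M2, dat$M3))
  D <- cbind(one, dat$X, dat$M1, dat$M2, dat$M3, Z)
  cD <- qr.coef(qr(D), dat$Y)
  c(a1 = unname(cA[2, 1]), a2 = unname(cB[2, 1]), a3 = unname(cB[2, 2]),
    d21 = unname(cB[3, 1]), d31 = unname(cB[3, 2]),
    b1 = unname(cD[3]), b2 = unname(cD[4]), b3 = unname(cD[5]),
    cPrime = unname(cD[2]), total = unname(cA[2, 2]))
}

#' Fit the serial-parallel path model (model-81 topology)
#'
#' Four ordinary least squares equations with a shared covariate set:
#' \code{M1 ~ X + C}, \code{M2 ~ X + M1 + C}, \code{M3 ~ X + M1 + C} and
#' \code{Y ~ X + M1 + M2 + M3 + C}. Heteroscedasticity-consistent (HC3)
#' standard errors are reported for every coefficient. With
#' \code{standardized = TRUE} (default) the five analysis variables are
#' z-scored before fitting so indirect effects are on the standardized
#' scale.
#'
#' @param data data.frame with columns \code{X}, \code{M1}, \code{M2},
#'   \code{M3}, \code{Y} (or use \code{roles} to map names).
#' @param covariates optional data.frame of control variables.
#' @param roles named character vector mapping \code{X}, \code{M1},
#'   \code{M2}, \code{M3}, \code{Y} to columns of \code{data}.
#' @param standardized z-score the analysis variables before fitting.
#' @return a \linkS4class{PathModel81}.
#' @export
fitPathModel81 <- function(data, covariates = NULL, roles = NULL,
                           standardized = TRUE) {
  if (!is.null(roles)) {
    data <- data.frame(X = data[[roles[["X"]]]], M1 = data[[roles[["M1"]]]],
                       M2 = data[[roles[["M2"]]]], M3 = data[[roles[["M3"]]]],
                       Y = data[[roles[["Y"]]]])
  }
  need <- c("X", "M1", "M2", "M3", "Y")
  stopifnot(all(need %in% names(data)))
  Zraw <- if (!is.null(covariates)) designMatrix(covariates) else NULL
  cc <- complete.cases(data[need]) &
    (if (is.null(Zraw)) TRUE else complete.cases(Zraw))
  dat <- data[cc, need]
  Z <- if (is.null(Zraw)) NULL else Zraw[cc, , drop = FALSE]
  n <- nrow(dat)
  maxPred <- 4 + if (is.null(Z)) 0 else ncol(Z)
  if (n <= maxPred + 2) stop("too few complete cases")
  if (standardized) dat[] <- lapply(dat, zvec)
  ds <- med81Designs(dat, Z)
  eqs <- list(M1 = list(ds$m1, dat$M1), M2 = list(ds$m2, dat$M2),
              M3 = list(ds$m3, dat$M3), Y = list(ds$y, dat$Y))
  tabs <- lapply(names(eqs), function(nm) {
    X <- eqs[[nm]][[1]]
    if (kappa(crossprod(X)) > 1e8) stop("collinearity beyond condition limit")
    y <- eqs[[nm]][[2]]
    fit <- lm.fit(X, y)
    dof <- n - fit$rank
    # HC3 sandwich covariance on the plain lm fit
    lmobj <- lm(y ~ X - 1)
    V <- sandwich::vcovHC(lmobj, type = "HC3")
    se <- sqrt(diag(V))
    est <- fit$coefficients
    tv <- est / se
    data.frame(equation = nm,
               term = c("(Intercept)", colnames(X)[-1]),
               estimate = unname(est), se = unname(se), t = unname(tv),
               p = unname(2 * pt(-abs(tv), dof)), dof = dof,
               row.names = NULL)
  })
  paths <- med81Paths(dat, Z)
  new("PathModel81", coefTable = do.call(rbind, tabs), paths = paths,
      n = n, standardized = standardized)
}

#' Indirect, direct and total effects of a model-81 fit
#'
#' Products of the fitted path coefficients: three single-mediator effects
#' (a1 b1, a2 b2, a3 b3), two serial effects through the first-stage
#' mediator (a1 d21 b2, a1 d31 b3), their sum, the direct effect and the
#' total effect. On fitted OLS coefficients
#' total = direct + sum(indirect) exactly.
#'
#' @param model a \linkS4class{PathModel81}.
#' @return an \linkS4class{IndirectEffects} (no CIs; see
#'   \code{\link{bootstrapIndirectEffects}}).
#' @export
indirectEffects <- function(model) {
  p <- pathCoefficients(model)
  e <- indirectFromPaths(p)
  new("IndirectEffects", effects = e,
      ci = matrix(numeric(0), 0, 2), level = NA_real_, nBoot = 0)
}

indirectFromPaths <- function(p) {
  e <- c(indirect_m1 = unname(p["a1"] * p["b1"]),
         indirect_m2 = unname(p["a2"] * p["b2"]),
         indirect_m3 = unname(p["a3"] * p["b3"]),
         serial_m1_m2 = unname(p["a1"] * p["d21"] * p["b2"]),
         serial_m1_m3 = unname(p["a1"] * p["d31"] * p["b3"]))
  c(e, total_indirect = sum(e), direct = unname(p["cPrime"]),
    total = unname(p["cPrime"]) + sum(e))
}

#' Percentile-bootstrap confidence intervals for the indirect effects
#'
#' Case resampling: subjects are resampled with replacement and all four
#' equations are refitted jointly per resample; percentile intervals are
#' reported for every effect. An effect is robust when its interval
#' excludes zero. Degenerate resamples (constant analysis variable) are
#' redrawn and counted.
#'
#' @param data,covariates,roles,standardized as in
#'   \code{\link{fitPathModel81}}.
#' @param nBoot bootstrap samples (at least 500 recommended; the study
#'   scale is 50000).
#' @param level confidence level (default 0.95).
#' @param seed seed.
#' @return an \linkS4class{IndirectEffects} with percentile CIs.
#' @export
bootstrapIndirectEffects <- function(data, covariates = NULL, roles = NULL,
                                     nBoot = 1000, level = 0.95,
                                     standardized = TRUE, seed = 1L) {
  model <- fitPathModel81(data, covariates, roles, standardized)
  if (!is.null(roles)) {
    data <- data.frame(X = data[[roles[["X"]]]], M1 = data[[roles[["M1"]]]],
                       M2 = data[[roles[["M2"]]]], M3 = data[[roles[["M3"]]]],
                       Y = data[[roles[["Y"]]]])
  }
  need <- c("X", "M1", "M2", "M3", "Y")
  Zraw <- if (!is.null(covariates)) designMatrix(covariates) else NULL
  cc <- complete.cases(data[need]) &
    (if (is.null(Zraw)) TRUE else complete.cases(Zraw))
  dat <- data[cc, need]
  Z <- if (is.null(Zraw)) NULL else Zraw[cc, , drop = FALSE]
  if (standardized) dat[] <- lapply(dat, zvec)
  n <- nrow(dat)
  set.seed(seed)
  draws <- matrix(NA_real_, nBoot, 8)
  redrawn <- 0
  b <- 1
  datM <- as.matrix(dat)
  while (b <= nBoot) {
    idx <- sample.int(n, replace = TRUE)
    di <- datM[idx, , drop = FALSE]
    if (any(apply(di, 2, sd) == 0)) {
      redrawn <- redrawn + 1
      next
    }
    Zi <- if (is.null(Z)) NULL else Z[idx, , drop = FALSE]
    dl <- list(X = di[, "X"], M1 = di[, "M1"], M2 = di[, "M2"],
               M3 = di[, "M3"], Y = di[, "Y"])
    draws[b, ] <- indirectFromPaths(med81Paths(dl, Zi))
    b <- b + 1
  }
  obs <- indirectFromPaths(pathCoefficients(model))
  ci <- t(apply(draws, 2, percentileCI, level = level))
  rownames(ci) <- names(obs)
  new("IndirectEffects", effects = obs, ci = ci, level = level,
      nBoot = nBoot)
}
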