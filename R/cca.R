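# Core CCA on pre-standardized matrices. Fast path: Cholesky whitening of
# the two correlation matrices and an SVD of the whitened cross-correlation
# (equivalent to the generalized eigenproblem); falls back to the pivoted-QR
# route when either block is numerically rank-deficient. Weights are scaled
# so training variates have unit variance.
ccaCore <- function(Xs, Ys) {
  n <- nrow(Xs)
  Cxx <- crossprod(Xs) / (n - 1)
  Cyy <- crossprod(Ys) / (n - 1)
  Rx <- tryCatch(chol(Cxx), error = function(e) NULL)
  Ry <- tryCatch(chol(Cyy), error = function(e) NULL)
  if (is.null(Rx) || is.null(Ry) ||
      min(diag(Rx)) < 1e-7 || min(diag(Ry)) < 1e-7)
    return(ccaCoreQR(Xs, Ys))
  Cxy <- crossprod(Xs, Ys) / (n - 1)
  # K = Rx^-T Cxy Ry^-1, whitened cross-correlation
  K <- backsolve(Rx, t(backsolve(Ry, t(Cxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(K)
  d <- min(ncol(Xs), ncol(Ys))
  A <- backsolve(Rx, sv$u[, seq_len(d), drop = FALSE])
  B <- backsolve(Ry, sv$v[, seq_len(d), drop = FALSE])
  list(A = A, B = B, cors = pmin(pmax(sv$d[seq_len(d)], 0), 1))
}

ccaCoreQR <- function(Xs, Ys) {
  n <- nrow(Xs)
  qx <- qr(Xs)
  qy <- qr(Ys)
  rx <- qx$rank
  ry <- qy$rank
  Qx <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  d <- min(rx, ry)
  # back-substitute through the R factors (pivoted QR)
  solveR <- function(q, U, r) {
    Rm <- qr.R(q)[seq_len(r), seq_len(r), drop = FALSE]
    W <- backsolve(Rm, U[, seq_len(d), drop = FALSE])
    out <- matrix(0, ncol(q$qr), d)
    out[q$pivot[seq_len(r)], ] <- W
    out
  }
  A <- solveR(qx, sv$u, rx) * sqrt(n - 1)
  B <- solveR(qy, sv$v, ry) * sqrt(n - 1)
  list(A = A, B = B, cors = pmin(pmax(sv$d[seq_len(d)], 0), 1))
}

#' Canonical correlation analysis
#'
#' Identifies maximally correlated linear combinations (variates) of two
#' variable sets. Columns are standardized internally; the solution is
#' equivalent to the generalized eigenproblem of
#' \eqn{\Sigma_{xx}^{-1}\Sigma_{xy}\Sigma_{yy}^{-1}\Sigma_{yx}} and is
#' computed by QR decomposition of both sets followed by an SVD. When
#' n <= p_x + p_y the fit is rank-regularized through the pivoted QR
#' (pseudo-inverse behaviour) with a warning. The sign of each weight
#' vector is fixed so its largest-magnitude element is positive.
#'
#' @param X,Y numeric matrices (subjects x variables).
#' @return a \linkS4class{CcaModel}.
#' @export
fitCca <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  for (nm in list(list(X, "X"), list(Y, "Y"))) {
    sds <- apply(nm[[1]], 2, sd)
    if (any(sds == 0)) {
      cols <- colnames(nm[[1]]) %||% seq_len(ncol(nm[[1]]))
      stop(sprintf("constant column in %s: %s", nm[[2]],
                   paste(cols[sds == 0], collapse = ", ")))
    }
  }
  if (nrow(X) <= ncol(X) + ncol(Y))
    warning("n <= p_x + p_y: rank-regularized (pseudo-inverse) solution")
  xc <- colMeans(X); xs <- apply(X, 2, sd)
  yc <- colMeans(Y); ys <- apply(Y, 2, sd)
  fit <- ccaCore(sweep(sweep(X, 2, xc), 2, xs, "/"),
                 sweep(sweep(Y, 2, yc), 2, ys, "/"))
  # deterministic sign: largest |weight| element of each x-vector positive
  for (j in seq_len(ncol(fit$A))) {
    s <- sign(fit$A[which.max(abs(fit$A[, j])), j])
    if (s < 0) {
      fit$A[, j] <- -fit$A[, j]
      fit$B[, j] <- -fit$B[, j]
    }
  }
  new("CcaModel", xWeights = fit$A, yWeights = fit$B, cors = fit$cors,
      xCenter = xc, xScale = xs, yCenter = yc, yScale = ys)
}

#' Project new data onto fitted canonical variates
#'
#' Applies the training-set standardization (means and SDs are re-used,
#' never refit) and the fitted weights to new observations of the X set.
#'
#' @param model a \linkS4class{CcaModel}.
#' @param Xnew matrix with the training columns in training order.
#' @param set \code{"x"} or \code{"y"}: which variable set \code{Xnew}
#'   belongs to.
#' @return matrix of variate scores (subjects x variates).
#' @export
projectVariate <- function(model, Xnew, set = c("x", "y")) {
  set <- match.arg(set)
  W <- if (set == "x") model@xWeights else model@yWeights
  ctr <- if (set == "x") model@xCenter else model@yCenter
  scl <- if (set == "x") model@xScale else model@yScale
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != nrow(W)) stop("column count mismatch with training set")
  sweep(sweep(Xnew, 2, ctr), 2, scl, "/") %*% W
}

# Internal: one full CV pass. Returns concatenated test-fold first-variate
# scores (original subject order). Lean by design: called inside the
# permutation loop.
cvCcaPass <- function(X, Y, Z, folds, k) {
  n <- nrow(X)
  sx <- numeric(n)
  sy <- numeric(n)
  refA <- NULL
  refB <- NULL
  resX <- X
  resY <- Y
  stdCols <- function(M, ctr, scl)
    (M - rep(ctr, each = nrow(M))) / rep(scl, each = nrow(M))
  for (f in seq_len(k)) {
    test <- folds == f
    train <- !test
    Xf <- X; Yf <- Y
    if (!is.null(Z)) {
      Xf <- residCv(X, Z, train)
      Yf <- residCv(Y, Z, train)
      resX[test, ] <- Xf[test, , drop = FALSE]
      resY[test, ] <- Yf[test, , drop = FALSE]
    }
    Xtr <- Xf[train, , drop = FALSE]
    Ytr <- Yf[train, , drop = FALSE]
    m <- nrow(Xtr)
    ctrx <- colMeans(Xtr)
    ctry <- colMeans(Ytr)
    sdx <- sqrt((colSums(Xtr^2) - m * ctrx^2) / (m - 1))
    sdy <- sqrt((colSums(Ytr^2) - m * ctry^2) / (m - 1))
    Xs <- stdCols(Xtr, ctrx, sdx)
    Ys <- stdCols(Ytr, ctry, sdy)
    fit <- ccaCore(Xs, Ys)
    a <- fit$A[, 1]
    b <- fit$B[, 1]
    if (is.null(refA)) {
      refA <- a
      refB <- b
    } else {
      # align fold signs to the first fold's weight vectors
      if (sum(a * refA) + sum(b * refB) < 0) {
        a <- -a
        b <- -b
      }
    }
    sx[test] <- stdCols(Xf[test, , drop = FALSE], ctrx, sdx) %*% a
    sy[test] <- stdCols(Yf[test, , drop = FALSE], ctry, sdy) %*% b
  }
  list(sx = sx, sy = sy, resX = resX, resY = resY)
}

# Residualize on confound design Z: coefficients fit on the training rows,
# applied to all rows (no test-fold leakage).
residCv <- function(V, Z, train) {
  qz <- qr(Z[train, , drop = FALSE])
  beta <- qr.coef(qz, V[train, , drop = FALSE])
  beta[is.na(beta)] <- 0
  V - Z %*% beta
}

# Fold assignment: k roughly equal folds, seeded.
makeFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

confoundDesign <- function(confounds, n) {
  if (is.null(confounds) || (is.data.frame(confounds) && !ncol(confounds)))
    return(NULL)
  cbind(`(Intercept)` = rep(1, n), designMatrix(confounds))
}

#' Cross-validated canonical correlation analysis
#'
#' Ten-fold (by default) cross-validation: confound residualization and
#' column standardization are fitted on the training folds and applied to
#' the left-out fold; the CCA weights from the training folds predict the
#' test-fold variates; test folds are concatenated (sign-aligned to the
#' first fold) and r_CV is the correlation of the concatenated predicted
#' first-variate pair.
#'
#' @param X,Y numeric matrices (subjects x variables).
#' @param confounds optional data.frame of confounds residualized out
#'   within the cross-validation (training-fold coefficients applied to
#'   test folds).
#' @param k number of folds (must satisfy k <= n/3).
#' @param seed integer seed for the fold assignment.
#' @return a \linkS4class{CvCcaResult} (permutation p and loadings are
#'   filled by \code{\link{ccaPermutationPvalue}} and
#'   \code{\link{bootstrapLoadings}}).
#' @export
crossValidateCca <- function(X, Y, confounds = NULL, k = 10, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (k > n / 3) stop("k must not exceed n/3")
  folds <- makeFolds(n, k, seed)
  Z <- confoundDesign(confounds, n)
  pass <- cvCcaPass(X, Y, Z, folds, k)
  new("CvCcaResult", scoresX = pass$sx, scoresY = pass$sy,
      rCV = cor(pass$sx, pass$sy), permP = NA_real_,
      loadings = data.frame(), folds = as.integer(folds),
      seed = as.integer(seed), residualX = pass$resX, residualY = pass$resY)
}

#' Permutation significance of the cross-validated canonical correlation
#'
#' Permutes the rows of the Y set against a fixed X (subject shuffle, or a
#' spatially constrained spin when rows are parcels) and re-runs the
#' entire cross-validation pipeline per permutation, including confound
#' residualization. p = (#\{|r_null| >= |r_obs|\} + 1)/(nPerm + 1),
#' two-sided.
#'
#' @param X,Y,confounds,k as in \code{\link{crossValidateCca}}.
#' @param result the observed \linkS4class{CvCcaResult}.
#' @param nPerm number of permutations (values below 100 warn).
#' @param spins optional \linkS4class{SpinNullSet}; when supplied the
#'   permutations are its spin rows (rows of X/Y must then be parcels).
#' @param seed seed for the permutation draws.
#' @return the result object with \code{permP} filled.
#' @export
ccaPermutationPvalue <- function(result, X, Y, confounds = NULL, k = 10,
                                 nPerm = 1000, spins = NULL, seed = 1L) {
  if (nPerm < 100) warning("fewer than 100 permutations: unstable p-value")
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  folds <- result@folds
  Z <- confoundDesign(confounds, n)
  set.seed(seed)
  if (!is.null(spins)) {
    pm <- spinPermutations(spins)
    if (ncol(pm) != n) stop("spin permutations must match row (parcel) count")
    draws <- pm[sample(nrow(pm), nPerm, replace = nrow(pm) < nPerm), ,
                drop = FALSE]
  } else {
    draws <- t(replicate(nPerm, sample.int(n)))
  }
  rNull <- vapply(seq_len(nPerm), function(b) {
    p <- cvCcaPass(X, Y[draws[b, ], , drop = FALSE], Z, folds, k)
    cor(p$sx, p$sy)
  }, numeric(1))
  initialize(result, permP = permPvalue(result@rCV, rNull))
}

#' Bootstrap confidence intervals for cross-validated loadings
#'
#' Loadings are the correlations between each observed
#' (confound-residualized) variable and the concatenated predicted variate
#' of its own set. Percentile intervals come from case resampling of
#' subjects; resamples with a degenerate (constant) variate are redrawn
#' and counted. A variable is robust when its interval excludes zero.
#'
#' @param result a \linkS4class{CvCcaResult}.
#' @param nBoot bootstrap samples.
#' @param level confidence level (default 0.99).
#' @param seed seed.
#' @return the result with the \code{loadings} table filled (variable,
#'   set, estimate, lo, hi, robust).
#' @export
bootstrapLoadings <- function(result, nBoot = 2000, level = 0.99,
                              seed = 1L) {
  sx <- result@scoresX
  sy <- result@scoresY
  RX <- result@residualX
  RY <- result@residualY
  n <- length(sx)
  obs <- c(drop(cor(RX, sx)), drop(cor(RY, sy)))
  set.seed(seed)
  redrawn <- 0
  draws <- matrix(NA_real_, nBoot, length(obs))
  b <- 1
  while (b <= nBoot) {
    idx <- sample.int(n, replace = TRUE)
    if (sd(sx[idx]) == 0 || sd(sy[idx]) == 0) {
      redrawn <- redrawn + 1
      next
    }
    draws[b, ] <- c(drop(cor(RX[idx, , drop = FALSE], sx[idx])),
                    drop(cor(RY[idx, , drop = FALSE], sy[idx])))
    b <- b + 1
  }
  ci <- t(apply(draws, 2, percentileCI, level = level))
  vars <- c(colnames(RX) %||% paste0("x", seq_len(ncol(RX))),
            colnames(RY) %||% paste0("y", seq_len(ncol(RY))))
  tab <- data.frame(variable = vars,
                    set = rep(c("x", "y"), c(ncol(RX), ncol(RY))),
                    estimate = obs, lo = ci[, 1], hi = ci[, 2],
                    robust = ci[, 1] > 0 | ci[, 2] < 0,
                    row.names = NULL)
  attr(tab, "redrawn") <- redrawn
  initialize(result, loadings = tab)
}

#' Standardized contributions of predictors to a variate
#'
#' Regression of the z-scored variate on the z-scored predictors plus
#' control variables; the predictor coefficients play the role of
#' standardized canonical coefficients (unique contributions).
#'
#' @param variate numeric variate scores.
#' @param predictors data.frame of predictors of interest (z-scored
#'   internally).
#' @param controls optional data.frame of control variables.
#' @param level confidence level for the coefficient intervals.
#' @return data.frame with term, estimate, se, t, p, lo, hi.
#' @export
standardizedContributions <- function(variate, predictors, controls = NULL,
                                      level = 0.95) {
  P <- zscoreColumns(designMatrix(predictors))
  y <- zvec(variate)
  n <- length(y)
  if (!is.null(controls)) {
    # partial out the controls (Frisch-Waugh); a predictor left with no
    # unique variance contributes a zero coefficient
    C <- designMatrix(controls)
    P <- residualizeFitApply(P, controls)
    y <- drop(residualizeFitApply(y, controls))
    dofAdj <- ncol(C)
  } else {
    dofAdj <- 0
  }
  resSd <- apply(P, 2, sd)
  spanned <- resSd < 1e-6
  if (any(spanned))
    warning("predictor(s) fully captured by the controls: ",
            paste(colnames(P)[spanned], collapse = ", "))
  Pk <- P[, !spanned, drop = FALSE]
  X <- cbind(1, Pk)
  if (n <= ncol(X) + dofAdj) stop("more predictors than subjects")
  if (kappa(crossprod(X)) > 1e8)
    stop("collinearity beyond condition limit")
  fit <- lm.fit(X, y)
  dof <- n - fit$rank - dofAdj
  sigma2 <- sum(fit$residuals^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  est <- sek <- setNames(numeric(ncol(P)), colnames(P))
  est[!spanned] <- fit$coefficients[-1]
  sek[!spanned] <- se[-1]
  sek[spanned] <- NA_real_
  tq <- qt(1 - (1 - level) / 2, dof)
  data.frame(term = colnames(P), estimate = unname(est), se = unname(sek),
             t = unname(est / sek), p = unname(2 * pt(-abs(est / sek), dof)),
             lo = unname(est - tq * sek), hi = unname(est + tq * sek),
             row.names = NULL)
}
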