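# Correlation matrix between standardized behavior and stacked brain
# conditions, and its SVD. Brain columns are blocks of R per condition.
plsCore <- function(brainS, behaviorS) {
  Rmat <- crossprod(behaviorS, brainS) / (nrow(brainS) - 1)
  sv <- svd(Rmat)
  list(u = sv$u, v = sv$v, d = sv$d)
}

#' Partial least squares correlation across stacked conditions
#'
#' Singular value decomposition of the correlation matrix between the
#' behavior set and the brain set, with the brain conditions (for example
#' two timepoints) stacked as blocks of columns. Brain saliences are unit
#' norm (R entries per condition); latent-variable scores are the data
#' projected on the saliences; covariance explained per latent variable is
#' its squared singular value over the sum of all squared singular values.
#'
#' @param brain subjects x (R * conditions) matrix.
#' @param behavior subjects x B matrix.
#' @param conditions number of stacked brain conditions (default 1).
#' @return a \linkS4class{PlsModel}.
#' @export
fitPls <- function(brain, behavior, conditions = 1L) {
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  if (ncol(behavior) == 0) stop("behavior set is empty")
  if (ncol(brain) %% conditions != 0)
    stop("brain columns must divide evenly into conditions")
  sds <- c(apply(brain, 2, sd), apply(behavior, 2, sd))
  if (any(sds == 0)) stop("constant column in brain or behavior set")
  bc <- colMeans(brain); bs <- apply(brain, 2, sd)
  yc <- colMeans(behavior); ys <- apply(behavior, 2, sd)
  brainS <- sweep(sweep(brain, 2, bc), 2, bs, "/")
  behaviorS <- sweep(sweep(behavior, 2, yc), 2, ys, "/")
  sv <- plsCore(brainS, behaviorS)
  # deterministic sign: largest |brain salience| element positive
  for (j in seq_along(sv$d)) {
    s <- sign(sv$v[which.max(abs(sv$v[, j])), j])
    if (s < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  new("PlsModel", brainSaliences = sv$v, behaviorSaliences = sv$u,
      singularValues = sv$d, covExplained = sv$d^2 / sum(sv$d^2),
      conditions = as.integer(conditions),
      brainCenter = bc, brainScale = bs,
      behaviorCenter = yc, behaviorScale = ys)
}

# Project data through a fitted PLS model: per-condition brain LV scores
# and behavior LV scores for latent variable `lv`.
plsScores <- function(model, brain, behavior, lv = 1L) {
  brainS <- sweep(sweep(as.matrix(brain), 2, model@brainCenter), 2,
                  model@brainScale, "/")
  behaviorS <- sweep(sweep(as.matrix(behavior), 2, model@behaviorCenter), 2,
                     model@behaviorScale, "/")
  C <- model@conditions
  R <- ncol(brainS) / C
  bscore <- sapply(seq_len(C), function(cc) {
    cols <- ((cc - 1) * R + 1):(cc * R)
    drop(brainS[, cols, drop = FALSE] %*%
           model@brainSaliences[cols, lv])
  })
  list(brain = as.matrix(bscore),
       behavior = drop(behaviorS %*% model@behaviorSaliences[, lv]))
}

#' Permutation significance of the PLS latent variables
#'
#' Null distribution of each singular value under row permutation of the
#' behavior set; p = (exceedances + 1)/(nPerm + 1) per latent variable.
#'
#' @param brain,behavior,conditions as in \code{\link{fitPls}}.
#' @param nPerm permutations (at least 100).
#' @param seed seed.
#' @return numeric vector of p-values, one per latent variable.
#' @export
plsPermutationPvalues <- function(brain, behavior, conditions = 1L,
                                  nPerm = 1000, seed = 1L) {
  if (nPerm < 100) stop("at least 100 permutations required")
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  brainS <- zscoreColumns(brain)
  behaviorS <- zscoreColumns(behavior)
  d0 <- plsCore(brainS, behaviorS)$d
  n <- nrow(brainS)
  set.seed(seed)
  exceed <- numeric(length(d0))
  for (b in seq_len(nPerm)) {
    dN <- plsCore(brainS, zscoreColumns(
      behaviorS[sample.int(n), , drop = FALSE]))$d
    exceed <- exceed + (dN >= d0)
  }
  (exceed + 1) / (nPerm + 1)
}

#' Bootstrap ratios for the PLS brain saliences
#'
#' Resamples subjects with replacement, refits the SVD, realigns each
#' resample's salience signs to the original solution, and reports the
#' bootstrap ratio (original salience / bootstrap SD) per brain element.
#' Elements with |BSR| above the threshold (default 2.75, similar to a
#' 99\% CI) form the reliable set. Behavior-correlation CIs (correlation
#' of each behavior variable with the brain LV scores, per condition) are
#' percentile intervals over the same resamples.
#'
#' @param model a fitted \linkS4class{PlsModel}.
#' @param brain,behavior the training data.
#' @param nBoot bootstrap samples (at least 100).
#' @param threshold reliability threshold on |BSR|.
#' @param level level for the behavior-correlation CIs.
#' @param seed seed.
#' @return list with \code{bsr} (per brain element), \code{reliable}
#'   (logical), \code{behaviorCor} (observed, per condition) and
#'   \code{behaviorCI}.
#' @export
plsBootstrapRatios <- function(model, brain, behavior, nBoot = 1000,
                               threshold = 2.75, level = 0.95, seed = 1L) {
  if (nBoot < 100) stop("at least 100 bootstrap samples required")
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  n <- nrow(brain)
  v0 <- model@brainSaliences[, 1]
  sc0 <- plsScores(model, brain, behavior)
  C <- model@conditions
  obsCor <- sapply(seq_len(C), function(cc)
    drop(cor(behavior, sc0$brain[, cc])))
  obsCor <- as.matrix(obsCor)
  set.seed(seed)
  vDraws <- matrix(NA_real_, nBoot, length(v0))
  cDraws <- array(NA_real_, c(nBoot, ncol(behavior), C))
  redrawn <- 0
  b <- 1
  while (b <= nBoot) {
    idx <- sample.int(n, replace = TRUE)
    bb <- brain[idx, , drop = FALSE]
    yy <- behavior[idx, , drop = FALSE]
    if (any(apply(yy, 2, sd) == 0) || any(apply(bb, 2, sd) == 0)) {
      redrawn <- redrawn + 1
      next
    }
    sv <- plsCore(zscoreColumns(bb), zscoreColumns(yy))
    v <- sv$v[, 1]
    if (sum(v * v0) < 0) v <- -v  # sign indeterminacy of the SVD
    vDraws[b, ] <- v
    R <- length(v0) / C
    for (cc in seq_len(C)) {
      cols <- ((cc - 1) * R + 1):(cc * R)
      s <- drop(zscoreColumns(bb)[, cols, drop = FALSE] %*% v[cols])
      cDraws[b, , cc] <- drop(cor(yy, s))
    }
    b <- b + 1
  }
  bsd <- apply(vDraws, 2, sd)
  bsr <- v0 / bsd
  ciList <- lapply(seq_len(C), function(cc)
    t(apply(cDraws[, , cc, drop = FALSE], 2, percentileCI, level = level)))
  list(bsr = bsr, reliable = abs(bsr) > threshold & bsd > 0,
       behaviorCor = obsCor, behaviorCI = ciList, redrawn = redrawn,
       threshold = threshold)
}

stdColsFast <- function(M, ctr, scl)
  (M - rep(ctr, each = nrow(M))) / rep(scl, each = nrow(M))

# Per-fold brain-side cache for the four-step cross-validation: the brain
# conditions and the confound projections do not change when the behavior
# set is permuted, so residualization, standardization and the training
# QR of the confound design are computed once and reused across the whole
# permutation loop.
cvPlsPrep <- function(brain, Z, folds, k) {
  lapply(seq_len(k), function(f) {
    test <- folds == f
    train <- !test
    Bf <- brain
    qrZ <- NULL
    if (!is.null(Z)) {
      qrZ <- qr(Z[train, , drop = FALSE])
      beta <- qr.coef(qrZ, brain[train, , drop = FALSE])
      beta[is.na(beta)] <- 0
      Bf <- brain - Z %*% beta
    }
    Btr <- Bf[train, , drop = FALSE]
    m <- nrow(Btr)
    bc <- colMeans(Btr)
    bs <- sqrt((colSums(Btr^2) - m * bc^2) / (m - 1))
    list(test = test, train = train, qrZ = qrZ,
         BtrStd = stdColsFast(Btr, bc, bs),
         BteStd = stdColsFast(Bf[test, , drop = FALSE], bc, bs),
         resBrainTest = Bf[test, , drop = FALSE])
  })
}

# One cross-validation pass of the four-step procedure given the brain
# cache: per training fold, saliences from the training cross-correlation
# SVD (sign-aligned to the first fold); test-fold brain data weighted per
# condition by the training brain saliences and behavior by the training
# behavior saliences. Scores are centered within fold (fold-level mean
# shifts shared through the common split would otherwise couple the sets).
cvPlsPassCached <- function(prep, behavior, Z, folds, k, C,
                            wantResid = FALSE) {
  n <- nrow(behavior)
  R <- ncol(prep[[1]]$BtrStd) / C
  brainScores <- matrix(NA_real_, n, C)
  behaviorScores <- numeric(n)
  refV <- NULL
  refU <- NULL
  resBehavior <- if (wantResid) behavior else NULL
  for (f in seq_len(k)) {
    pf <- prep[[f]]
    test <- pf$test
    train <- pf$train
    Yf <- behavior
    if (!is.null(Z)) {
      beta <- qr.coef(pf$qrZ, behavior[train, , drop = FALSE])
      beta[is.na(beta)] <- 0
      Yf <- behavior - Z %*% beta
      if (wantResid) resBehavior[test, ] <- Yf[test, , drop = FALSE]
    }
    Ytr <- Yf[train, , drop = FALSE]
    m <- nrow(Ytr)
    yc <- colMeans(Ytr)
    ys <- sqrt((colSums(Ytr^2) - m * yc^2) / (m - 1))
    sv <- plsCore(pf$BtrStd, stdColsFast(Ytr, yc, ys))
    v <- sv$v[, 1]
    u <- sv$u[, 1]
    if (is.null(refV)) {
      refV <- v
      refU <- u
    } else if (sum(v * refV) + sum(u * refU) < 0) {
      v <- -v
      u <- -u
    }
    for (cc in seq_len(C)) {
      cols <- ((cc - 1) * R + 1):(cc * R)
      brainScores[test, cc] <- pf$BteStd[, cols, drop = FALSE] %*% v[cols]
    }
    behaviorScores[test] <- stdColsFast(Yf[test, , drop = FALSE], yc, ys) %*% u
  }
  for (f in seq_len(k)) {
    test <- prep[[f]]$test
    brainScores[test, ] <- sweep(brainScores[test, , drop = FALSE], 2,
                                 colMeans(brainScores[test, , drop = FALSE]))
    behaviorScores[test] <- behaviorScores[test] -
      mean(behaviorScores[test])
  }
  list(brainScores = brainScores, behaviorScores = behaviorScores,
       resBehavior = resBehavior)
}

# Convenience wrapper (one-shot pass without an external cache).
cvPlsPass <- function(brain, behavior, Z, folds, k, C, wantResid = FALSE) {
  prep <- cvPlsPrep(brain, Z, folds, k)
  out <- cvPlsPassCached(prep, behavior, Z, folds, k, C, wantResid)
  if (wantResid)
    out$resBrain <- {
      rb <- brain
      for (f in seq_len(k)) rb[prep[[f]]$test, ] <- prep[[f]]$resBrainTest
      rb
    }
  out
}

#' Cross-validated PLS correlation with within-condition permutation
#'
#' Ten-fold cross-validation of the PLS model in four steps: (1) test-fold
#' brain data in each condition are weighted by the training-fold brain
#' saliences; (2) test-fold behavior scores are weighted by the
#' training-fold behavior saliences; (3) the singular value decomposition
#' of the correlation between the predicted brain LV scores (one column
#' per condition) and the predicted behavior LV summarizes the
#' cross-validated association; (4) significance comes from permuting the
#' behavior set with a single subject permutation applied identically in
#' every condition (preserving the interdependence of the per-condition
#' brain scores) and re-running the cross-validated weighting per
#' permutation, so the null distribution carries the same fold-overlap
#' optimism as the observed statistic. Per-condition correlations of the behavior variates with
#' the predicted brain LV are reported with percentile bootstrap CIs, and
#' a per-parcel loading map (correlation of each parcel's residualized
#' data with the predicted brain LV of its condition).
#'
#' @param brain subjects x (R * conditions) matrix.
#' @param behavior subjects x B matrix.
#' @param conditions number of stacked conditions.
#' @param confounds optional data.frame; residualization is fitted on
#'   training folds and applied to test folds, for both sets.
#' @param k folds; \code{seed} controls folds, permutations and bootstrap.
#' @param nPerm permutations for step (4).
#' @param nBoot bootstrap samples for the correlation CIs.
#' @param level CI level (default 0.95).
#' @param seed integer seed.
#' @return a \linkS4class{CvPlsResult}.
#' @export
crossValidatePls <- function(brain, behavior, conditions = 2L,
                             confounds = NULL, k = 10, nPerm = 1000,
                             nBoot = 1000, level = 0.95, seed = 1L) {
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  n <- nrow(brain)
  if (nrow(behavior) != n) stop("condition subject mismatch")
  C <- as.integer(conditions)
  R <- ncol(brain) / C
  folds <- makeFolds(n, k, seed)
  Z <- confoundDesign(confounds, n)
  prep <- cvPlsPrep(brain, Z, folds, k)
  pass <- cvPlsPassCached(prep, behavior, Z, folds, k, C, wantResid = TRUE)
  brainScores <- pass$brainScores
  behaviorScores <- pass$behaviorScores
  resBrain <- brain
  for (f in seq_len(k)) resBrain[prep[[f]]$test, ] <- prep[[f]]$resBrainTest
  resBehavior <- if (is.null(Z)) behavior else pass$resBehavior
  corMat <- matrix(cor(resBehavior, brainScores),
                   ncol(behavior), C,
                   dimnames = list(colnames(behavior) %||%
                                     paste0("b", seq_len(ncol(behavior))),
                                   paste0("condition", seq_len(C))))
  # step (3): SVD of the cross-validated score correlation; step (4): null
  # via one shared subject permutation of the behavior set, re-running the
  # whole cross-validated weighting so the null carries the same
  # fold-overlap optimism as the observed statistic
  svObs <- svd(cor(cbind(behaviorScores), brainScores))$d[1]
  set.seed(seed + 1L)
  svNull <- vapply(seq_len(nPerm), function(b) {
    idx <- sample.int(n)  # one ordering, applied to behavior only
    pn <- cvPlsPassCached(prep, behavior[idx, , drop = FALSE], Z, folds,
                          k, C)
    svd(cor(cbind(pn$behaviorScores), pn$brainScores))$d[1]
  }, numeric(1))
  permP <- (sum(svNull >= svObs) + 1) / (nPerm + 1)
  # bootstrap CIs for the per-condition behavior-variate correlations
  set.seed(seed + 2L)
  draws <- array(NA_real_, c(nBoot, ncol(behavior), C))
  b <- 1
  while (b <= nBoot) {
    idx <- sample.int(n, replace = TRUE)
    if (any(apply(brainScores[idx, , drop = FALSE], 2, sd) == 0) ||
        sd(behaviorScores[idx]) == 0) next
    draws[b, , ] <- cor(resBehavior[idx, , drop = FALSE],
                        brainScores[idx, , drop = FALSE])
    b <- b + 1
  }
  cis <- do.call(rbind, lapply(seq_len(C), function(cc) {
    ci <- t(apply(draws[, , cc, drop = FALSE], 2, percentileCI,
                  level = level))
    data.frame(variable = rownames(corMat), condition = cc,
               estimate = corMat[, cc], lo = ci[, 1], hi = ci[, 2],
               robust = ci[, 1] > 0 | ci[, 2] < 0, row.names = NULL)
  }))
  lmap <- sapply(seq_len(C), function(cc) {
    cols <- ((cc - 1) * R + 1):(cc * R)
    drop(cor(resBrain[, cols, drop = FALSE], brainScores[, cc]))
  })
  new("CvPlsResult", brainScores = brainScores,
      behaviorScores = behaviorScores, corByCondition = corMat,
      permP = permP, cis = cis, loadingMap = as.matrix(lmap),
      folds = as.integer(folds), seed = as.integer(seed))
}
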