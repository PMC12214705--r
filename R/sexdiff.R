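#' Fit the adult sexual-differentiation template
#'
#' Regresses every connectivity edge on biological sex (coded +1 male,
#' -1 female) and the adjustment covariates with ordinary least squares;
#' the template entry for an edge is the t-statistic of the sex
#' coefficient, so positive values mark edges with consistently stronger
#' coupling in males. Collinear covariate columns are dropped with a
#' warning.
#'
#' @param fc R x R x n array of Fisher-z connectivity matrices.
#' @param pheno data.frame with a \code{sex} column (+1/-1) and the
#'   covariates.
#' @param covariates character vector of covariate column names; defaults
#'   to every column except \code{subject} and \code{sex}.
#' @return a \linkS4class{SexDiffTemplate}.
#' @export
fitSexDiffTemplate <- function(fc, pheno, covariates = NULL) {
  sex <- pheno$sex
  if (length(unique(sex)) < 2) stop("both sexes must be present")
  if (!all(sex %in% c(-1, 1))) stop("sex must be coded +1 male / -1 female")
  covariates <- covariates %||%
    setdiff(names(pheno), c("subject", "sex"))
  Z <- designMatrix(pheno[covariates])
  X <- cbind(`(Intercept)` = 1, sex = sex, Z)
  n <- nrow(X)
  if (n <= ncol(X) + 1) stop("more covariates than subjects support")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear covariates dropped: ",
            paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  E <- edgeMatrix(fc)
  beta <- qr.coef(qx, E)
  res <- E - X %*% beta
  dof <- n - ncol(X)
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qx))
  sexVar <- XtXinv[which(colnames(X) == "sex"), which(colnames(X) == "sex")]
  tstat <- beta[which(colnames(X) == "sex"), ] / sqrt(sigma2 * sexVar)
  R <- dim(fc)[1]
  new("SexDiffTemplate", tstat = edgesToMatrix(tstat, R), dof = dof,
      covariates = covariates)
}

#' Score a subject's regional similarity to the template
#'
#' For each region, the Spearman correlation (average ranks for ties)
#' between the subject's regional connectivity profile (their row of the
#' Fisher-z matrix) and the corresponding row of the template t-statistic
#' matrix, over off-diagonal entries. Positive values indicate a more
#' masculine regional coupling pattern. Rows with fewer than 4 valid pairs
#' yield \code{NA}.
#'
#' @param fc R x R Fisher-z matrix for one subject.
#' @param template a \linkS4class{SexDiffTemplate}.
#' @return length-R numeric vector of Spearman correlations in [-1, 1].
#' @export
scoreSexDiff <- function(fc, template) {
  tm <- tstatMatrix(template)
  R <- nrow(tm)
  if (!all(dim(fc) == dim(tm))) stop("parcel count mismatch with template")
  vapply(seq_len(R), function(i) {
    spearman(fc[i, -i], tm[i, -i])
  }, numeric(1))
}

#' Score a whole cohort against the template
#'
#' Vectorized equivalent of \code{\link{scoreSexDiff}} applied to every
#' subject of an R x R x n connectivity array: template row ranks are
#' computed once and each subject's row ranks are correlated against them.
#'
#' @param fcArray R x R x n array of Fisher-z matrices.
#' @param template a \linkS4class{SexDiffTemplate}.
#' @return subjects x R matrix of regional profiles.
#' @export
scoreCohortSexDiff <- function(fcArray, template) {
  tm <- tstatMatrix(template)
  R <- nrow(tm)
  n <- dim(fcArray)[3]
  idx <- t(vapply(seq_len(R), function(i) setdiff(seq_len(R), i),
                  integer(R - 1)))
  Trow <- matrix(tm[cbind(rep(seq_len(R), R - 1), as.vector(idx))], R)
  TrkC <- t(apply(Trow, 1, rank))
  TrkC <- TrkC - rowMeans(TrkC)
  denomT <- sqrt(rowSums(TrkC^2))
  flat <- cbind(rep(seq_len(R), R - 1), as.vector(idx))
  out <- matrix(NA_real_, n, R)
  for (s in seq_len(n)) {
    fc <- fcArray[, , s]
    M <- matrix(fc[flat], R)
    Mrk <- t(apply(M, 1, rank))
    Mc <- Mrk - rowMeans(Mrk)
    out[s, ] <- rowSums(Mc * TrkC) / (sqrt(rowSums(Mc^2)) * denomT)
  }
  out
}

#' Align a regional map to the planted or supplied axis
#'
#' Spearman correlation between a length-R regional map and the axis
#' ranks, with significance from spatially constrained (spin)
#' permutations: two-sided p = (#\{|rho_null| >= |rho_obs|\} + 1) /
#' (n_spins + 1).
#'
#' @param map length-R regional values.
#' @param axisRanks length-R axis ranks or scores.
#' @param spins a \linkS4class{SpinNullSet}.
#' @return list with \code{rho} and \code{pSpin}.
#' @export
alignToAxis <- function(map, axisRanks, spins) {
  if (length(map) != length(axisRanks)) stop("length mismatch")
  if (sd(map, na.rm = TRUE) == 0) stop("constant map rejected")
  res <- spinPvalue(map, axisRanks, spins)
  list(rho = res$statObs, pSpin = res$p)
}

#' Regional maps of partial Spearman correlations
#'
#' For every supplied measure, computes one length-R map: the partial
#' Spearman correlation between the per-region differentiation index and
#' the measure, adjusted for the confounds. All variables are
#' rank-transformed (average ranks), the ranks are residualized on the
#' confound ranks/dummies by ordinary least squares, and Pearson
#' correlations of the residuals are reported. A measure that is constant
#' after residualization yields a map of missing values with a warning.
#'
#' @param profiles subjects x R matrix of regional differentiation indices.
#' @param measures data.frame of named measure columns.
#' @param confounds data.frame of confounds (numeric columns are ranked;
#'   categorical columns dummy-coded).
#' @return R x nMeasures matrix of partial correlations.
#' @export
mapPartialCorrelations <- function(profiles, measures, confounds) {
  n <- nrow(profiles)
  if (n < 10) stop("at least 10 subjects required")
  rankNum <- function(x) rank(x, ties.method = "average")
  Zparts <- lapply(confounds, function(col) {
    if (is.numeric(col)) rankNum(col) else designMatrix(data.frame(v = col))
  })
  Z <- do.call(cbind, Zparts)
  P <- apply(profiles, 2, rankNum)
  Pres <- residualizeFitApply(P, Z)
  out <- sapply(names(measures), function(nm) {
    m <- rankNum(measures[[nm]])
    mres <- residualizeFitApply(m, Z)
    if (sd(mres) < 1e-12) {
      warning(sprintf("measure '%s' constant after residualization", nm))
      return(rep(NA_real_, ncol(profiles)))
    }
    drop(cor(mres, Pres))
  })
  rownames(out) <- colnames(profiles) %||% seq_len(ncol(profiles))
  out
}
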