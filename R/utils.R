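#' @import stats
#' @importFrom utils read.delim write.table
NULL

# Column z-score; constant columns are rejected by callers where that matters.
zscoreColumns <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  sweep(sweep(x, 2, ctr, "-"), 2, sds, "/")
}

zvec <- function(x) (x - mean(x)) / sd(x)

# Dummy-coded design matrix (no intercept column) from a data.frame or
# matrix. Zero-variance columns (for example a rare-event flag that never
# fires in the sample) are dropped: they carry no adjustment information
# and would make downstream solves singular.
designMatrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], factor)
  mm <- model.matrix(~., data = df)
  mm <- mm[, -1, drop = FALSE]
  keep <- apply(mm, 2, function(x) length(unique(x)) > 1)
  mm[, keep, drop = FALSE]
}

# Residualize values (vector or matrix) on covariates; optionally fit on a
# training subset and apply to all rows. Orthogonality to the covariate span is
# asserted to 1e-8 on the fitting rows.
residualizeFitApply <- function(values, covariates, fitRows = NULL) {
  V <- as.matrix(values)
  Z <- cbind(`(Intercept)` = rep(1, nrow(V)), designMatrix(covariates))
  if (is.null(fitRows)) fitRows <- seq_len(nrow(V))
  qz <- qr(Z[fitRows, , drop = FALSE])
  rankDef <- qz$rank < ncol(Z)
  if (rankDef) warning("rank-deficient covariate matrix; pseudo-inverse used")
  beta <- qr.coef(qz, V[fitRows, , drop = FALSE])
  beta[is.na(beta)] <- 0
  res <- V - Z %*% beta
  fitted <- Z[fitRows, , drop = FALSE]
  ortho <- crossprod(scale(fitted, scale = FALSE),
                     res[fitRows, , drop = FALSE])
  stopifnot(max(abs(ortho)) < 1e-6 * max(1, max(abs(V))) * nrow(V))
  res
}

# Lower-triangle (i > j) index pairs of an R x R matrix.
lowerTriIndex <- function(R) {
  idx <- which(lower.tri(matrix(0, R, R)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# Flatten a stack of symmetric matrices (R x R x n) to n x nEdges.
edgeMatrix <- function(fcArray) {
  R <- dim(fcArray)[1]
  n <- dim(fcArray)[3]
  lt <- lower.tri(matrix(0, R, R))
  t(apply(fcArray, 3, function(m) m[lt]))
}

# Rebuild a symmetric matrix (diagonal NA) from a lower-triangle vector.
edgesToMatrix <- function(edges, R) {
  m <- matrix(NA_real_, R, R)
  m[lower.tri(m)] <- edges
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4) return(NA_real_)
  cor(rank(x[ok]), rank(y[ok]))
}

# Two-sided permutation p with the +1 correction.
permPvalue <- function(statObs, statNull) {
  (sum(abs(statNull) >= abs(statObs)) + 1) / (length(statNull) + 1)
}

# Percentile CI from a vector of bootstrap replicates.
percentileCI <- function(draws, level) {
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), na.rm = TRUE, type = 6))
}

# Read/write numeric matrices as TSV with row labels in the first column.
writeTsvMatrix <- function(m, path, idColumn = "parcel_id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsvMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
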