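#' Framewise displacement from six rigid-body motion parameters
#'
#' Backward-difference framewise displacement: the sum of absolute
#' translation changes (mm) plus the head-radius-projected sum of absolute
#' rotation changes (radians), with the first frame set to 0.
#'
#' @param motion frames x 6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param headRadiusMm sphere radius used to project rotations (default 50).
#' @param fdThreshold threshold (mm) for the fraction-below summary.
#' @return list with \code{fd} (per frame), \code{meanFd},
#'   \code{maxParamExcursion} (mm, rotations projected) and
#'   \code{fracBelow}.
#' @export
framewiseDisplacement <- function(motion, headRadiusMm = 50,
                                  fdThreshold = 0.20) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (nrow(motion) < 2) stop("at least 2 frames required")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  proj <- cbind(motion[, 1:3, drop = FALSE],
                headRadiusMm * motion[, 4:6, drop = FALSE])
  excursion <- max(apply(proj, 2, function(x) diff(range(x))))
  list(fd = fd, meanFd = mean(fd), maxParamExcursion = excursion,
       fracBelow = mean(fd < fdThreshold))
}

#' Band-stop filter motion regressors in the respiratory band
#'
#' Removes signal in the respiratory-artifact frequency band (default
#' 0.31-0.43 Hz) from each motion parameter with a zero-phase
#' (forward-backward) Butterworth band-stop filter, preserving DC and
#' out-of-band content.
#'
#' @param motion frames x 6 motion parameter matrix.
#' @param bandHz length-2 stop band in Hz.
#' @param trSeconds repetition time in seconds.
#' @param order Butterworth order of the underlying IIR design (default 4;
#'   applied forward and backward).
#' @return filtered matrix of the same dimensions.
#' @export
filterMotionRegressors <- function(motion, bandHz = c(0.31, 0.43),
                                   trSeconds, order = 4) {
  motion <- as.matrix(motion)
  nyquist <- 1 / (2 * trSeconds)
  if (max(bandHz) >= nyquist)
    stop(sprintf("stop band must lie below the Nyquist frequency (%.3f Hz)",
                 nyquist))
  bf <- signal::butter(order, bandHz / nyquist, type = "stop")
  out <- apply(motion, 2, function(x) {
    mu <- mean(x)
    mu + signal::filtfilt(bf, x - mu)
  })
  dimnames(out) <- dimnames(motion)
  out
}

#' Expand six motion parameters to the 24-regressor set
#'
#' Returns the six parameters, their backward-difference first derivatives
#' (first row 0), and the squares of those twelve columns: 24 regressors.
#'
#' @param motion frames x 6 motion parameter matrix (typically filtered).
#' @return frames x 24 matrix.
#' @export
expandMotionTerms <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  deriv <- rbind(0, diff(motion))
  out <- cbind(motion, deriv, motion^2, deriv^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("dm", 1:6),
                     paste0("m", 1:6, "_sq"), paste0("dm", 1:6, "_sq"))
  out
}

#' Regress nuisance signals out of parcel time series
#'
#' Ordinary least squares removal of the supplied nuisance columns
#' (tissue means, trend terms, motion regressors) from every parcel time
#' series; an intercept is always included. Residuals are orthogonal to the
#' nuisance columns; a rank-deficient nuisance set falls back to the
#' pseudo-inverse with a warning.
#'
#' @param ts frames x R parcel time-series matrix.
#' @param nuisance frames x q nuisance matrix.
#' @return residual time-series matrix (same dimensions as \code{ts}).
#' @export
regressNuisance <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts))
    stop("nuisance frame count must match time series")
  X <- cbind(1, nuisance)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("rank-deficient nuisance matrix; pseudo-inverse used")
  beta <- qr.coef(qx, ts)
  beta[is.na(beta)] <- 0
  res <- ts - X %*% beta
  Xc <- scale(X[, -1, drop = FALSE], scale = FALSE)
  stopifnot(max(abs(crossprod(Xc, res))) <
              1e-8 * max(1, max(abs(ts))) * nrow(ts))
  res
}

#' Pairwise Fisher-z functional connectivity
#'
#' Pearson correlations between all parcel time series, Fisher
#' z-transformed with |r| clipped to 1 - 1e-7 so the transform stays
#' finite; the diagonal (self-coupling) is masked as \code{NA}. Parcels
#' with zero variance have all their edges set missing, with a warning.
#'
#' @param ts frames x R time-series matrix (at least 20 frames).
#' @return R x R symmetric Fisher-z matrix with \code{NA} diagonal.
#' @export
computeFc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 20) stop("at least 20 frames required")
  v <- apply(ts, 2, var)
  bad <- v <= 0 | !is.finite(v)
  r <- suppressWarnings(cor(ts))
  if (any(bad)) {
    warning(sprintf("%d zero-variance parcel(s); their edges set missing",
                    sum(bad)))
    r[bad, ] <- NA
    r[, bad] <- NA
  }
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- NA_real_
  z
}

#' Average Fisher-z connectivity across runs
#'
#' Elementwise mean in z-space; edges missing in some runs are averaged
#' over the runs where they are available.
#'
#' @param runs list of R x R Fisher-z matrices of equal dimension.
#' @return R x R averaged matrix, diagonal \code{NA}.
#' @export
averageFc <- function(runs) {
  if (length(runs) == 0) stop("empty run list")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("runs must share dimensions")
  sums <- Reduce(`+`, lapply(runs, function(m) ifelse(is.na(m), 0, m)))
  cnts <- Reduce(`+`, lapply(runs, function(m) !is.na(m)))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  diag(out) <- NA_real_
  out
}

#' Edge-wise QC-FC motion diagnostics
#'
#' Correlates every connectivity edge with subjects' mean framewise
#' displacement, summarizes the distribution (median absolute QC-FC), and
#' quantifies distance dependence as the Spearman correlation between the
#' edge-wise QC-FC values and inter-centroid Euclidean distance, with a
#' permutation null check (FD shuffled across subjects).
#'
#' @param fcStack R x R x n array of Fisher-z matrices.
#' @param meanFd per-subject mean framewise displacement.
#' @param geometry parcel geometry (for centroid distances); optional.
#' @param nNull permutations for the null width check.
#' @param seed seed for the permutation null.
#' @return list with \code{edgeCor}, \code{medianAbs},
#'   \code{distanceRho}, \code{nullRho} (permutation draws) and the edge
#'   index used.
#' @export
qcFc <- function(fcStack, meanFd, geometry = NULL, nNull = 100, seed = 1L) {
  n <- dim(fcStack)[3]
  if (n < 10) stop("at least 10 subjects required")
  if (var(meanFd) <= 0) stop("degenerate input: mean FD is constant")
  E <- edgeMatrix(fcStack)
  edgeCor <- drop(cor(meanFd, E))
  out <- list(edgeCor = edgeCor, medianAbs = median(abs(edgeCor), na.rm = TRUE))
  if (!is.null(geometry)) {
    R <- dim(fcStack)[1]
    xyz <- as.matrix(geometry[, c("x", "y", "z")])
    D <- as.matrix(dist(xyz))
    dEdges <- D[lower.tri(D)]
    out$distanceRho <- spearman(edgeCor, dEdges)
    set.seed(seed)
    out$nullRho <- replicate(nNull, {
      ec <- drop(cor(sample(meanFd), E))
      spearman(ec, dEdges)
    })
  }
  out
}

#' Apply the head-motion exclusion criteria
#'
#' A subject is retained only if mean framewise displacement is strictly
#' below \code{meanFdMax}, at least \code{fracBelow} of frames have FD
#' strictly below the frame threshold, and the maximum single-parameter
#' excursion is strictly below \code{maxMotionMm}. Subjects with missing
#' motion summaries are excluded with a logged reason.
#'
#' @param summaries data.frame with columns \code{subject}, \code{meanFd},
#'   \code{fracBelow}, \code{maxMotion}.
#' @param meanFdMax mean-FD ceiling in mm (default 0.20).
#' @param fracBelow required fraction of frames under the FD threshold
#'   (default 0.80).
#' @param maxMotionMm maximum allowed excursion in mm (default 5).
#' @return list with \code{retained} (subject ids) and \code{log}
#'   (data.frame of per-subject decisions and reasons).
#' @export
applyMotionExclusion <- function(summaries, meanFdMax = 0.20,
                                 fracBelow = 0.80, maxMotionMm = 5) {
  reasons <- character(nrow(summaries))
  ok <- logical(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (anyNA(s[c("meanFd", "fracBelow", "maxMotion")])) {
      reasons[i] <- "missing motion summary"
    } else if (!(s$meanFd < meanFdMax)) {
      reasons[i] <- sprintf("mean FD %.3f not < %.2f", s$meanFd, meanFdMax)
    } else if (!(s$fracBelow >= fracBelow)) {
      reasons[i] <- sprintf("only %.0f%% frames below threshold",
                            100 * s$fracBelow)
    } else if (!(s$maxMotion < maxMotionMm)) {
      reasons[i] <- sprintf("max motion %.1f mm not < %g", s$maxMotion,
                            maxMotionMm)
    } else {
      ok[i] <- TRUE
      reasons[i] <- "retained"
    }
  }
  list(retained = summaries$subject[ok],
       log = data.frame(subject = summaries$subject, retained = ok,
                        reason = reasons))
}
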