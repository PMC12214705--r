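# Haar-uniform rotation: QR of a Gaussian matrix with sign correction,
# determinant forced to +1.
haarRotation <- function() {
  z <- matrix(rnorm(9), 3)
  qrz <- qr(z)
  q <- qr.Q(qrz)
  q <- q %*% diag(sign(diag(qr.R(qrz))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Greedy one-to-one assignment, closest pairs first: returns perm such that
# original parcel i takes the value of parcel perm[i] after the spin.
greedyMatch <- function(original, rotated) {
  m <- nrow(original)
  D <- as.matrix(dist(rbind(original, rotated)))[seq_len(m),
                                                 m + seq_len(m)]
  perm <- integer(m)
  for (step in seq_len(m)) {
    k <- arrayInd(which.min(D), dim(D))
    perm[k[1]] <- k[2]
    D[k[1], ] <- Inf
    D[, k[2]] <- Inf
  }
  perm
}

#' Generate hemisphere-paired spatially constrained permutations
#'
#' For each permutation a uniform random 3D rotation is applied to the
#' left-hemisphere centroids (which live on that hemisphere's own full
#' registration sphere) and its x-mirrored counterpart to the right
#' hemisphere; the rotated centroids are matched one-to-one to the
#' nearest original same-hemisphere centroids, closest pairs assigned
#' first. Every row of the result is a hemisphere-preserving bijection,
#' so spun maps keep their value multiset and (approximately) their
#' spatial autocorrelation.
#'
#' @param geometry parcel geometry data.frame (\code{hemisphere},
#'   \code{x}, \code{y}, \code{z}).
#' @param nPerm number of permutations (positive).
#' @param seed integer seed.
#' @return a \linkS4class{SpinNullSet}.
#' @export
generateSpins <- function(geometry, nPerm, seed = 1L) {
  if (nPerm <= 0) stop("nPerm must be positive")
  set.seed(seed)
  hemi <- geometry$hemisphere
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  idxL <- which(hemi == "L")
  idxR <- which(hemi == "R")
  sphL <- xyz[idxL, , drop = FALSE]
  sphR <- xyz[idxR, , drop = FALSE]
  mirror <- diag(c(-1, 1, 1))
  perms <- matrix(NA_integer_, nPerm, nrow(geometry))
  for (b in seq_len(nPerm)) {
    rot <- haarRotation()
    rotR <- mirror %*% rot %*% mirror  # mirrored rotation for the right
    pL <- greedyMatch(sphL, sphL %*% t(rot))
    pR <- greedyMatch(sphR, sphR %*% t(rotR))
    perm <- integer(nrow(geometry))
    perm[idxL] <- idxL[pL]
    perm[idxR] <- idxR[pR]
    perms[b, ] <- perm
  }
  new("SpinNullSet", perms = perms, hemisphere = hemi,
      seed = as.integer(seed))
}

#' Spin-permutation test for the association of two regional maps
#'
#' The first map is spun (its values permuted by the spatially constrained
#' permutations) while the second stays fixed;
#' p = (#\{|stat_null| >= |stat_obs|\} + 1)/(nPerm + 1), two-sided.
#'
#' @param mapA,mapB length-R regional maps.
#' @param spins a \linkS4class{SpinNullSet}.
#' @param stat \code{"spearman"} (default) or \code{"pearson"}.
#' @return list with \code{statObs}, \code{p} and the null draws.
#' @export
spinPvalue <- function(mapA, mapB, spins, stat = c("spearman", "pearson")) {
  stat <- match.arg(stat)
  pm <- spinPermutations(spins)
  if (length(mapA) != ncol(pm) || length(mapB) != ncol(pm))
    stop("map length must match the spin geometry")
  if (sd(mapA, na.rm = TRUE) == 0 || sd(mapB, na.rm = TRUE) == 0)
    stop("constant map rejected")
  a <- if (stat == "spearman") rank(mapA) else mapA
  b <- if (stat == "spearman") rank(mapB) else mapB
  statObs <- cor(a, b)
  statNull <- vapply(seq_len(nrow(pm)), function(i) {
    cor(a[pm[i, ]], b)
  }, numeric(1))
  list(statObs = statObs, p = permPvalue(statObs, statNull),
       null = statNull)
}
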