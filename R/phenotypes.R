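#' Residualize values on covariates
#'
#' Ordinary least squares residuals of one or more columns on a covariate
#' set (dummy-coded, intercept included). Residuals are orthogonal to the
#' covariate span; a rank-deficient covariate matrix falls back to the
#' pseudo-inverse with a warning.
#'
#' @param values numeric vector or matrix.
#' @param covariates data.frame or matrix of covariates.
#' @return residuals with the dimensions of \code{values}.
#' @export
residualize <- function(values, covariates) {
  V <- as.matrix(values)
  Z <- designMatrix(covariates)
  if (nrow(V) <= ncol(Z) + 1)
    stop("too few rows for the covariate count")
  res <- residualizeFitApply(V, covariates)
  if (is.vector(values)) unname(drop(res)) else res
}

#' Hormonal indices of adrenarche and gonadarche
#'
#' Within each sex, hormone levels are residualized for saliva
#' quality-related covariates (plus menstrual covariates for girls where
#' the fields are available), z-scored within sex, and combined:
#' adrenarche is the mean of standardized DHEA and testosterone in girls
#' and standardized DHEA in boys; gonadarche is standardized estradiol in
#' girls and standardized testosterone in boys. Indices are then pooled
#' across sexes.
#'
#' @param panel data.frame with \code{dhea}, \code{testosterone},
#'   \code{estradiol} (girls only) columns.
#' @param sex +1 male / -1 female per subject.
#' @param salivaCovariates data.frame of saliva quality covariates.
#' @param menarcheFields optional data.frame of menstrual covariates
#'   (girls); missing fields are skipped with a warning.
#' @param restandardize if TRUE (default) the combined indices are
#'   re-standardized within sex so each pooled index has within-sex mean 0
#'   and SD 1; if FALSE the definitional combination (for example a girl's
#'   adrenarche as the plain mean of her z-scored DHEA and testosterone)
#'   is returned unscaled.
#' @return data.frame with \code{hormonal_adrenarche},
#'   \code{hormonal_gonadarche}; within-sex mean 0 and SD 1 before
#'   pooling when \code{restandardize} is TRUE.
#' @export
hormonalIndices <- function(panel, sex, salivaCovariates,
                            menarcheFields = NULL, restandardize = TRUE) {
  n <- nrow(panel)
  adren <- gonad <- rep(NA_real_, n)
  for (s in c(-1, 1)) {
    idx <- which(sex == s)
    cov <- salivaCovariates[idx, , drop = FALSE]
    if (s == -1 && !is.null(menarcheFields)) {
      mf <- menarcheFields[idx, , drop = FALSE]
      usable <- vapply(mf, function(x) !anyNA(x), logical(1))
      if (!all(usable))
        warning("menstrual covariate(s) with missing values skipped: ",
                paste(names(mf)[!usable], collapse = ", "))
      cov <- cbind(cov, mf[usable])
    }
    zres <- function(x) {
      ok <- !is.na(x)
      out <- rep(NA_real_, length(x))
      r <- residualize(x[ok], cov[ok, , drop = FALSE])
      out[ok] <- (r - mean(r)) / sd(r)
      out
    }
    zd <- zres(panel$dhea[idx])
    zt <- zres(panel$testosterone[idx])
    if (s == -1) {
      ze <- zres(panel$estradiol[idx])
      adren[idx] <- rowMeans(cbind(zd, zt))
      gonad[idx] <- ze
    } else {
      adren[idx] <- zd
      gonad[idx] <- zt
    }
    if (restandardize) {
      rz <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
      adren[idx] <- rz(adren[idx])
      gonad[idx] <- rz(gonad[idx])
    }
  }
  data.frame(hormonal_adrenarche = adren, hormonal_gonadarche = gonad)
}

#' Self-reported indices of adrenarche and gonadarche
#'
#' Adrenarche is the mean of the skin-change and body-hair items for both
#' sexes; gonadarche is the mean of growth spurt, breast development and
#' menarche in girls and of growth spurt, voice deepening and facial hair
#' in boys. Missing items are dropped from the mean; a construct with all
#' items missing is \code{NA}.
#'
#' @param pdsItems data.frame with columns \code{pds_skin},
#'   \code{pds_body_hair}, \code{pds_growth_spurt}, \code{pds_breast},
#'   \code{pds_menarche}, \code{pds_voice}, \code{pds_facial_hair}.
#' @param sex +1 male / -1 female.
#' @return data.frame with \code{selfreport_adrenarche},
#'   \code{selfreport_gonadarche}.
#' @export
selfReportIndices <- function(pdsItems, sex) {
  meanAvail <- function(m) {
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  adren <- meanAvail(as.matrix(pdsItems[c("pds_skin", "pds_body_hair")]))
  girls <- sex == -1
  gonad <- rep(NA_real_, nrow(pdsItems))
  gg <- as.matrix(pdsItems[c("pds_growth_spurt", "pds_breast",
                             "pds_menarche")])
  gb <- as.matrix(pdsItems[c("pds_growth_spurt", "pds_voice",
                             "pds_facial_hair")])
  gonad[girls] <- meanAvail(gg[girls, , drop = FALSE])
  gonad[!girls] <- meanAvail(gb[!girls, , drop = FALSE])
  data.frame(selfreport_adrenarche = adren, selfreport_gonadarche = gonad)
}

#' Standardized change scores between two assessment waves
#'
#' Each scale is z-scored within wave on the analysis sample and the
#' change score is the difference of the standardized scores
#' (later minus earlier). A scale constant at either wave is rejected.
#'
#' @param t2Scores,t3Scores data.frames of the same scales for the same
#'   subjects at the two waves.
#' @return data.frame of change scores, one column per scale.
#' @export
changeScores <- function(t2Scores, t3Scores) {
  stopifnot(identical(dim(t2Scores), dim(t3Scores)))
  out <- lapply(seq_along(t2Scores), function(j) {
    a <- t2Scores[[j]]
    b <- t3Scores[[j]]
    if (sd(a) == 0 || sd(b) == 0)
      stop(sprintf("scale '%s' constant at a wave", names(t2Scores)[j]))
    zvec(b) - zvec(a)
  })
  names(out) <- sub("_t2$", "", names(t2Scores))
  as.data.frame(out)
}
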