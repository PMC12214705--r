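#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-data generators: cohort sizes,
#' parcel count, acquisition parameters, the planted
#' sensorimotor-association (S-A) axis, the sex-effect scale, the causal
#' path coefficients of the polygenic-risk -> T1 brain -> T2 physiology ->
#' symptom-change chain, per-layer noise standard deviations, per-SNP minor
#' allele frequencies and the Gompertz mortality parameters.
#'
#' The default path coefficients (0.5 each, no direct effect) plant a
#' strong, unambiguous causal chain; the default per-edge connectivity
#' noise (0.25 in Fisher-z units) and per-region differentiation gain
#' (0.08 per unit latent) were chosen by an a-priori power analysis so the
#' planted chain is detectable at the default cohort sizes while individual
#' edges remain noisy, as in real resting-state data.
#'
#' @param nRefAdults adult reference cohort size.
#' @param nAdolescents adolescent cohort size.
#' @param nRois number of parcels (even, at least 8).
#' @param nFrames frames per run; \code{nRuns} runs; \code{trSeconds} TR.
#' @param nRuns runs per timepoint.
#' @param trSeconds repetition time in seconds.
#' @param axisRanks optional length-\code{nRois} planted S-A axis ranks;
#'   by default derived from parcel geometry (rank of the z coordinate,
#'   mirrored across hemispheres) so the axis is spatially smooth.
#' @param sexEffectScale edge-level sex effect scale: the male-minus-female
#'   mean difference on edge (i, j) is
#'   \code{sexEffectScale * (ar_i + ar_j + 2 * axisInteraction * ar_i * ar_j)}
#'   with \code{ar} the standardized axis scores.
#' @param axisInteraction weight of the axis interaction in the sex effect.
#'   A purely additive sex effect (weight 0) gives every regional
#'   connectivity profile the same signal-to-noise along the axis -- rank
#'   correlations are location and scale invariant per row -- so regional
#'   differentiation would be flat along the axis; the interaction term
#'   plants the axis gradient of differentiation magnitude that the
#'   regional similarity statistic is designed to detect.
#' @param brainLoadScale per-region differentiation gain per unit of the
#'   latent brain score along the axis.
#' @param brainStability correlation of the T1 and T2 latent brain scores.
#' @param pathCoefficients list with \code{prsToBrain}, \code{brainToPhysio},
#'   \code{physioToSymptom}, \code{direct}; all latents are unit variance so
#'   products are implied correlations.
#' @param noiseSd list of positive SDs: \code{fcEdge}, \code{hormone},
#'   \code{biomarker}, \code{cbcl}.
#' @param maf per-SNP minor allele frequencies in (0.05, 0.5); recycled.
#' @param gompertz list with \code{b0}, \code{bAge}, \code{bBiomarkers}
#'   (length 8, standardized scale), \code{gamma}, \code{horizonYears}.
#' @param nMortality mortality reference cohort size.
#' @param fcFromTimeSeries if TRUE adolescent FC is materialized from
#'   simulated run-wise time series through the connectivity module instead
#'   of directly at the matrix level.
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(nRefAdults = 400, nAdolescents = 500, nRois = 100,
                      nFrames = 200, nRuns = 3, trSeconds = 0.8,
                      axisRanks = NULL, sexEffectScale = 0.3,
                      axisInteraction = 0.28,
                      brainLoadScale = 0.08, brainStability = 0.6,
                      pathCoefficients = list(prsToBrain = 0.5,
                                              brainToPhysio = 0.5,
                                              physioToSymptom = 0.5,
                                              direct = 0),
                      noiseSd = list(fcEdge = 0.25, hormone = 0.6,
                                     biomarker = 0.6, cbcl = 0.8),
                      maf = NULL,
                      gompertz = list(b0 = -8.15, bAge = 0.11,
                                      bBiomarkers = c(0.6, -0.65, 0.7,
                                                      -0.6, 0.75, -0.7,
                                                      0.65, 0.6),
                                      gamma = 0.2, horizonYears = 15),
                      nMortality = 5000, fcFromTimeSeries = FALSE,
                      seed = 1L) {
  if (nRois < 8 || nRois %% 2 != 0)
    stop("nRois must be even and at least 8")
  sds <- unlist(noiseSd)
  if (any(sds <= 0)) stop("all noise SDs must be positive")
  if (trSeconds <= 0) stop("trSeconds must be positive")
  if (gompertz$gamma <= 0) stop("gompertz gamma must be positive")
  if (gompertz$horizonYears <= 0) stop("gompertz horizon must be positive")
  if (length(gompertz$bBiomarkers) != 8)
    stop("gompertz bBiomarkers must have length 8")
  if (!is.null(axisRanks) && length(axisRanks) != nRois)
    stop("axisRanks must have length nRois")
  if (!is.null(maf) && any(maf <= 0.05 | maf >= 0.5))
    stop("maf values must lie in (0.05, 0.5)")
  pc <- pathCoefficients
  if (any(!is.finite(unlist(pc)))) stop("non-finite path coefficient")
  structure(list(nRefAdults = nRefAdults, nAdolescents = nAdolescents,
                 nRois = nRois, nFrames = nFrames, nRuns = nRuns,
                 trSeconds = trSeconds, axisRanks = axisRanks,
                 sexEffectScale = sexEffectScale,
                 axisInteraction = axisInteraction,
                 brainLoadScale = brainLoadScale,
                 brainStability = brainStability,
                 pathCoefficients = pc, noiseSd = noiseSd, maf = maf,
                 gompertz = gompertz, nMortality = nMortality,
                 fcFromTimeSeries = fcFromTimeSeries,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Reference physiological ranges for the 8 blood-chemistry biomarkers.
biomarkerReference <- function() {
  data.frame(
    name = c("mcv", "rbc", "rdw", "wbc", "lymphocyte_pct", "monocyte_pct",
             "hba1c", "total_cholesterol"),
    mean = c(89, 4.7, 13.1, 6.8, 31, 8, 5.2, 170),
    sd = c(4.5, 0.4, 0.9, 1.7, 7, 2, 0.35, 30),
    lo = c(70, 3.2, 10.5, 2.5, 8, 2, 3.9, 80),
    hi = c(105, 6.2, 18, 15, 55, 16, 7.5, 300))
}

truncNorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate quasi-uniform parcel centroids on the unit sphere
#'
#' Places \code{nRois / 2} centroids per hemisphere with a Fibonacci
#' lattice over each hemisphere's own full unit sphere (the analogue of
#' the per-hemisphere spherical registration surface on which spin
#' rotations act; a half-sphere layout is not closed under rotation and
#' would make spatially constrained permutations ill-defined near the
#' boundary). The left hemisphere is the x-mirror of the right; a small
#' seeded angular jitter (re-normalized) makes distinct seeds give
#' distinct but equally regular layouts.
#'
#' @param nRois even parcel count, at least 8.
#' @param seed integer seed.
#' @return data.frame with \code{parcel_id}, \code{hemisphere} ("L"/"R"),
#'   and unit-norm \code{x}, \code{y}, \code{z}.
#' @export
generateParcelGeometry <- function(nRois, seed = 1L) {
  if (nRois %% 2 != 0 || nRois < 8)
    stop("nRois must be even and at least 8 (one half per hemisphere)")
  set.seed(seed)
  m <- nRois / 2
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m               # full sphere: z spans (-1, 1)
  phi <- golden * seq_len(m)
  rho <- sqrt(pmax(0, 1 - z^2))
  base <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  jitter <- function(p) {
    p <- p + matrix(rnorm(length(p), sd = 0.01), ncol = 3)
    p / sqrt(rowSums(p^2))
  }
  right <- jitter(base)
  left <- jitter(cbind(-base[, 1], base[, 2:3]))
  geom <- data.frame(parcel_id = seq_len(nRois),
                     hemisphere = rep(c("L", "R"), each = m),
                     rbind(left, right))
  colnames(geom)[3:5] <- c("x", "y", "z")
  geom
}

# Planted axis scores: use configured ranks, else a spatially smooth default
# (rank of the z coordinate) so spins preserve its autocorrelation.
axisScores <- function(config, geometry) {
  ranks <- config$axisRanks %||% rank(geometry$z, ties.method = "first")
  as.numeric(scale(ranks))
}

# Bilinear planted structure: edge (i,j) mean is m_i * ar_j + m_j * ar_i.
bilinearFC <- function(m, ar, sigma) {
  R <- length(ar)
  fc <- outer(m, ar) + outer(ar, m) +
    matrix(rnorm(R * R, sd = sigma * sqrt(2)), R)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- NA_real_
  fc
}

# Materialize a target Fisher-z matrix as run-wise Gaussian time series and
# rebuild it through the connectivity module (correlation + Fisher + run
# averaging). The target correlation is ridge-regularized to the nearest
# usable positive-definite matrix before the Cholesky draw.
fcViaTimeSeries <- function(targetZ, nFrames, nRuns) {
  R <- nrow(targetZ)
  C <- tanh(targetZ)
  diag(C) <- 1
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-4) {
    # clip the spectrum and restore a unit diagonal
    C <- eg$vectors %*% (pmax(eg$values, 1e-4) * t(eg$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  ch <- chol(C)
  runs <- lapply(seq_len(nRuns), function(r)
    computeFc(matrix(rnorm(nFrames * R), nFrames) %*% ch))
  averageFc(runs)
}

#' Generate the adult reference cohort
#'
#' Subjects carry an R x R Fisher-z connectivity matrix whose edge (i, j)
#' mean differs between the sexes by
#' \code{sexEffectScale * (ar_i + ar_j + 2 * axisInteraction * ar_i *
#' ar_j)} (masculine-positive on high-axis edges, with differentiation
#' magnitude increasing along the axis), plus the covariates used by the
#' template regression.
#'
#' @param config a \code{\link{simConfig}}.
#' @param geometry parcel geometry from \code{\link{generateParcelGeometry}}.
#' @return list with \code{fc} (R x R x n array), \code{pheno} (data.frame,
#'   no missing values, sex coded +1 male / -1 female) and \code{axis}.
#' @export
generateReferenceCohort <- function(config, geometry) {
  n <- config$nRefAdults
  R <- config$nRois
  nCov <- 14  # sex + 13 adjustment covariates in the template regression
  if (n < 2 * (nCov + 2))
    stop("nRefAdults too small: template regression would be rank-deficient")
  set.seed(config$seed + 1L)
  ar <- axisScores(config, geometry)
  sex <- sample(rep(c(1, -1), length.out = n))
  pheno <- data.frame(
    subject = sprintf("ref%04d", seq_len(n)),
    sex = sex,
    age = runif(n, 22, 35),
    income = exp(rnorm(n, log(55000), 0.4)),
    education = pmin(pmax(round(rnorm(n, 15, 2)), 10), 21),
    employment = rbinom(n, 1, 0.75),
    race = rbinom(n, 1, 0.35),
    handedness = rbinom(n, 1, 0.1),
    asr_depression = truncNorm(n, 50, 10, 30, 90),
    asr_anxiety = truncNorm(n, 50, 10, 30, 90),
    asr_adhd = truncNorm(n, 50, 10, 30, 90),
    asr_antisocial = truncNorm(n, 50, 10, 30, 90),
    asr_somatic = truncNorm(n, 50, 10, 30, 90),
    asr_avoidant = truncNorm(n, 50, 10, 30, 90),
    mean_fd = exp(rnorm(n, log(0.12), 0.35)),
    cog_fluid = truncNorm(n, 100, 15, 55, 145),
    cog_crystallized = truncNorm(n, 100, 15, 55, 145))
  fc <- array(NA_real_, c(R, R, n))
  halfScale <- 0.5 * config$sexEffectScale
  v <- 1 + config$axisInteraction * ar  # axis-modulated sex gain
  for (s in seq_len(n)) {
    fc[, , s] <- bilinearFC(halfScale * sex[s] * v, ar,
                            config$noiseSd$fcEdge)
  }
  list(fc = fc, pheno = pheno, axis = ar)
}

#' Generate the adolescent cohort with the planted causal chain
#'
#' Realizes a linear-Gaussian chain with unit-variance latents: polygenic
#' risk (anxiety) -> T1 latent brain differentiation (expressed regionally
#' along the planted axis) -> T2 physiology composite (expressed in the
#' blood-chemistry biomarkers, gonadal/adrenal hormones, pubertal
#' self-reports, BMI and deprivation) -> change in internalizing symptom
#' scores between the T2 and T3 assessments. Path coefficients come from
#' \code{config$pathCoefficients}; with unit-variance latents the implied
#' correlation between the risk score and the symptom change latent is the
#' product of the three path coefficients plus the direct effect.
#'
#' @param config a \code{\link{simConfig}}.
#' @param geometry parcel geometry.
#' @return list with \code{pheno} (data.frame), \code{fcT1}, \code{fcT2}
#'   (R x R x n arrays), \code{genotypes} (per-disorder list with dosage
#'   matrix, weights, allele metadata), and \code{truth} (planted latents
#'   and parameters).
#' @export
generateAdolescentCohort <- function(config, geometry) {
  pc <- config$pathCoefficients
  if (any(!is.finite(unlist(pc)))) stop("non-finite path coefficient")
  n <- config$nAdolescents
  R <- config$nRois
  set.seed(config$seed + 2L)
  ar <- axisScores(config, geometry)
  sex <- sample(rep(c(1, -1), length.out = n))
  girls <- sex == -1

  # genotypes and polygenic scores (SNPs independent; no LD structure)
  snpCounts <- c(mdd = 7L, anx = 3L, adhd = 12L)
  genotypes <- lapply(snpCounts, function(k) {
    maf <- config$maf %||% runif(k, 0.1, 0.45)
    maf <- rep_len(maf, k)
    dos <- sapply(maf, function(p) rbinom(n, 2, p))
    pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    al <- do.call(rbind, sample(pairs, k, replace = TRUE))
    list(dosages = dos, weights = rnorm(k, 0, 0.15), maf = maf,
         effectAllele = al[, 1], otherAllele = al[, 2])
  })
  prs <- vapply(genotypes, function(g)
    drop(g$dosages %*% g$weights), numeric(n))
  colnames(prs) <- paste0("prs_", names(snpCounts))
  prsz <- zvec(prs[, "prs_anx"])

  # unit-variance latent chain
  a <- pc$prsToBrain; b <- pc$brainToPhysio; cc <- pc$physioToSymptom
  clip1 <- function(x) sqrt(max(0, 1 - x^2))
  b1 <- a * prsz + clip1(a) * rnorm(n)
  stab <- config$brainStability
  b2 <- stab * b1 + clip1(stab) * rnorm(n)
  f2 <- b * b1 + clip1(b) * rnorm(n)
  resid <- max(0, 1 - cc^2 - pc$direct^2)
  ylat <- cc * f2 + pc$direct * prsz + sqrt(resid) * rnorm(n)

  # regional expression: per-region gain m_i = sex term + axis-weighted latent
  halfScale <- 0.5 * config$sexEffectScale
  kappa <- config$brainLoadScale
  v <- 1 + config$axisInteraction * ar
  fcT1 <- array(NA_real_, c(R, R, n))
  fcT2 <- array(NA_real_, c(R, R, n))
  for (s in seq_len(n)) {
    m1 <- halfScale * sex[s] * v + kappa * b1[s] * ar
    m2 <- halfScale * sex[s] * v + kappa * b2[s] * ar
    fcT1[, , s] <- bilinearFC(m1, ar, config$noiseSd$fcEdge)
    fcT2[, , s] <- bilinearFC(m2, ar, config$noiseSd$fcEdge)
    if (config$fcFromTimeSeries) {
      fcT1[, , s] <- fcViaTimeSeries(fcT1[, , s], config$nFrames,
                                     config$nRuns)
      fcT2[, , s] <- fcViaTimeSeries(fcT2[, , s], config$nFrames,
                                     config$nRuns)
    }
  }

  # saliva / menstrual covariates feeding the hormone residualization
  salivaDelayH <- runif(n, 0.5, 8)
  caffeineMg <- rpois(n, 20)
  activityFlag <- rbinom(n, 1, 0.2)
  salivaQuality <- rbinom(n, 1, 0.95)  # 1 = no concerns
  menarcheAge <- ifelse(girls, truncNorm(n, 11.5, 1, 9, 14), NA)
  daysSinceCycle <- ifelse(girls, runif(n, 0, 40), NA)
  cycleRegular <- ifelse(girls, rbinom(n, 1, 0.6), NA)

  hsd <- config$noiseSd$hormone
  hormone <- function(load, tabF, tabM) {
    z <- load * f2 + 0.1 * zvec(salivaDelayH) - 0.1 * zvec(caffeineMg) +
      hsd * rnorm(n)
    raw <- ifelse(girls,
                  tabF[1] + tabF[2] * z,
                  tabM[1] + tabM[2] * z)
    lo <- ifelse(girls, tabF[3], tabM[3])
    hi <- ifelse(girls, tabF[4], tabM[4])
    pmin(pmax(raw, lo), hi)
  }
  # means/SDs/ranges follow the reported T1/T2 assay summaries (pg/mL)
  dheaT1 <- hormone(0, c(77.2, 43.1, 5, 190), c(61.1, 41.6, 8, 216))
  dheaT2 <- hormone(0.5, c(115.5, 67.7, 13, 370), c(84.4, 69.3, 3, 315))
  testT1 <- hormone(0, c(37.3, 16.1, 5, 73), c(37.0, 23.6, 8, 224))
  testT2 <- hormone(0.5, c(51.7, 21.3, 14, 113), c(54.6, 33.5, 11, 169))
  estrT1 <- ifelse(girls, pmin(pmax(1.01 + 0.45 * (0 * f2 + rnorm(n)),
                                    0.13), 2.53), NA)
  estrT2 <- ifelse(girls, pmin(pmax(1.15 + 0.63 * (0.5 * f2 +
                                                     hsd * rnorm(n)),
                                    0.34), 5.29), NA)

  # separate item sets per wave: T1 reflects an earlier maturation latent
  # (independent of the planted chain), T2 reflects the physiology latent
  mat1 <- rnorm(n)
  pdsWave <- function(latent, load, suffix, base) {
    item <- function() {
      z <- load * latent + 0.6 * rnorm(n)
      pmin(pmax(round(base + z), 1), 4)
    }
    pds <- data.frame(
      skin = item(), body_hair = item(), growth_spurt = item(),
      voice = item(), facial_hair = item(), breast = item(),
      menarche = item())
    pds$voice[girls] <- NA
    pds$facial_hair[girls] <- NA
    pds$breast[!girls] <- NA
    pds$menarche[!girls] <- NA
    names(pds) <- paste0("pds_", names(pds), "_", suffix)
    pds
  }
  pds <- cbind(pdsWave(mat1, 0.4, "t1", base = 1.6),
               pdsWave(f2, 0.5, "t2", base = 2))

  bm <- biomarkerReference()
  lambdaB <- 0.45 * sign(config$gompertz$bBiomarkers)
  bsd <- config$noiseSd$biomarker
  biomarkers <- sapply(seq_len(8), function(k) {
    z <- lambdaB[k] * f2 + bsd * rnorm(n)
    pmin(pmax(bm$mean[k] + bm$sd[k] * z, bm$lo[k]), bm$hi[k])
  })
  colnames(biomarkers) <- bm$name

  bmi <- pmax(14, 19 + 3.2 * (0.45 * f2 + sqrt(1 - 0.45^2) * rnorm(n)))
  deprivation <- rbinom(n, 7, plogis(-1.5 + 0.5 * f2))
  medicalVisits <- rpois(n, exp(0.3 + 0.25 * f2))

  csd <- config$noiseSd$cbcl
  scales9 <- c("anxiety", "depression", "somatic", "adhd", "odd",
               "conduct", "ocd", "ptsd", "sct")
  internalizing <- scales9 %in% c("anxiety", "depression", "somatic")
  cbclT2 <- sapply(seq_along(scales9), function(j)
    pmax(0, 3 + 2.5 * rnorm(n)))
  cbclT3 <- sapply(seq_along(scales9), function(j) {
    zt2 <- zvec(cbclT2[, j])
    load <- if (internalizing[j]) 0.5 else 0
    pmax(0, 3 + 2.5 * (0.6 * zt2 + load * ylat + csd * rnorm(n)))
  })
  colnames(cbclT2) <- paste0("cbcl_", scales9, "_t2")
  colnames(cbclT3) <- paste0("cbcl_", scales9, "_t3")

  pheno <- data.frame(
    subject = sprintf("sub%04d", seq_len(n)),
    sex = sex,
    age_months_t1 = round(runif(n, 108, 131)),
    site = sample(paste0("site", 1:3), n, TRUE),
    race = rbinom(n, 1, 0.35),
    handedness = rbinom(n, 1, 0.1),
    adopted = rbinom(n, 1, 0.01),
    ambiguous_sex = rbinom(n, 1, 0.005),
    mean_fd_t1 = exp(rnorm(n, log(0.13), 0.35)),
    mean_fd_t2 = exp(rnorm(n, log(0.12), 0.35)),
    prs,
    dhea_t1 = dheaT1, dhea_t2 = dheaT2,
    testosterone_t1 = testT1, testosterone_t2 = testT2,
    estradiol_t1 = estrT1, estradiol_t2 = estrT2,
    saliva_delay_h = salivaDelayH, caffeine_mg = caffeineMg,
    activity_flag = activityFlag, saliva_quality = salivaQuality,
    menarche_age = menarcheAge, days_since_cycle = daysSinceCycle,
    cycle_regular = cycleRegular,
    pds,
    biomarkers,
    bmi = bmi, deprivation = deprivation, medical_visits = medicalVisits,
    cbclT2, cbclT3)
  pheno$age_months_t2 <- pheno$age_months_t1 + 24

  truth <- list(axis = ar, prsz = prsz, b1 = b1, b2 = b2, f2 = f2,
                ylat = ylat, paths = pc, sexEffectScale = config$sexEffectScale,
                brainLoadScale = kappa)
  list(pheno = pheno, fcT1 = fcT1, fcT2 = fcT2, genotypes = genotypes,
       truth = truth)
}

#' Generate a Gompertz mortality reference cohort
#'
#' Event times follow the proportional-hazards Gompertz model
#' \eqn{h(t) = \exp(b_0 + b_{age} a + \sum_k b_k z_k) e^{\gamma t}} with
#' administrative censoring at the configured horizon. Biomarkers are stored
#' on their physiological scales; the configured standardized coefficients
#' are converted to per-raw-unit coefficients internally.
#'
#' @param config a \code{\link{simConfig}}.
#' @return data.frame with the 8 biomarkers, \code{chronological_age},
#'   \code{follow_up} (> 0) and logical \code{died}.
#' @export
generateMortalityCohort <- function(config) {
  g <- config$gompertz
  if (g$gamma <= 0) stop("gamma must be positive")
  if (g$horizonYears <= 0) stop("negative or zero horizon rejected")
  set.seed(config$seed + 3L)
  n <- config$nMortality
  bm <- biomarkerReference()
  age <- runif(n, 20, 40)
  z <- matrix(rnorm(n * 8), n)
  raw <- sweep(sweep(z, 2, bm$sd, "*"), 2, bm$mean, "+")
  colnames(raw) <- bm$name
  lp <- g$b0 + g$bAge * age + drop(z %*% g$bBiomarkers)
  u <- runif(n)
  t <- log(1 - g$gamma * log(u) / exp(lp)) / g$gamma
  died <- t < g$horizonYears
  followUp <- pmin(t, g$horizonYears)
  data.frame(subject = sprintf("mort%05d", seq_len(n)), raw,
             chronological_age = age, follow_up = followUp, died = died)
}

#' Polygenic risk score as a weighted sum of risk-allele dosages
#'
#' Computes, per subject, the weighted sum of risk-allele dosages over the
#' SNPs that survive the standard filters: minor allele frequency at or
#' above the threshold, no insertion/deletion variants, and no
#' strand-ambiguous (A/T or G/C) pairs.
#'
#' @param dosages subjects x SNPs matrix of risk-allele counts in {0,1,2}.
#' @param weights per-SNP effect weights aligned to the dosage columns.
#' @param effectAllele,otherAllele optional allele metadata enabling the
#'   ambiguity/indel filters.
#' @param maf optional per-SNP minor allele frequencies; computed from the
#'   dosages when missing.
#' @param mafThreshold minimum minor allele frequency (default 0.05).
#' @return list with \code{scores} (per subject) and \code{retained}
#'   (indices of SNPs that contributed).
#' @export
scorePrs <- function(dosages, weights, effectAllele = NULL,
                     otherAllele = NULL, maf = NULL, mafThreshold = 0.05) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(weights))
    stop("weights must align with SNP columns")
  if (any(dosages != round(dosages) | dosages < 0 | dosages > 2))
    stop("dosages must be integral in {0, 1, 2}")
  keep <- rep(TRUE, ncol(dosages))
  if (is.null(maf)) {
    f <- colMeans(dosages) / 2
    maf <- pmin(f, 1 - f)
  }
  keep <- keep & maf >= mafThreshold
  if (!is.null(effectAllele)) {
    ambiguous <- (effectAllele == "A" & otherAllele == "T") |
      (effectAllele == "T" & otherAllele == "A") |
      (effectAllele == "G" & otherAllele == "C") |
      (effectAllele == "C" & otherAllele == "G")
    indel <- nchar(effectAllele) > 1 | nchar(otherAllele) > 1
    keep <- keep & !ambiguous & !indel
  }
  if (!any(keep))
    stop("no SNPs retained after filtering: empty panel")
  scores <- drop(dosages[, keep, drop = FALSE] %*% weights[keep])
  list(scores = scores, retained = which(keep))
}
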