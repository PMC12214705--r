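test_that("parcel geometry meets the dimension and uniqueness contracts", {
  g <- generateParcelGeometry(8, seed = 1L)
  expect_equal(nrow(g), 8)
  expect_equal(as.vector(table(g$hemisphere)[c("L", "R")]), c(4L, 4L))
  norms <- sqrt(g$x^2 + g$y^2 + g$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_identical(g, generateParcelGeometry(8, seed = 1L))

  g2 <- generateParcelGeometry(100, seed = 7L)
  xyz <- as.matrix(g2[, c("x", "y", "z")])
  D <- tcrossprod(xyz)
  D[D > 1] <- 1
  ang <- acos(D)
  diag(ang) <- Inf
  expect_gt(min(ang), 0)  # brute-force pairwise: no duplicated centroids
  expect_error(generateParcelGeometry(9, seed = 1L), "even")
})

test_that("reference cohort plants the configured sex effect", {
  # null case: no sex effect, edge-wise two-sample t rejects at ~5%
  cfg0 <- tinyConfig(seed = 5L, sexEffectScale = 0)
  geom <- generateParcelGeometry(cfg0$nRois, cfg0$seed)
  ref0 <- generateReferenceCohort(cfg0, geom)
  E <- neuroSexDiff:::edgeMatrix(ref0$fc)
  male <- ref0$pheno$sex == 1
  pvals <- apply(E, 2, function(e) t.test(e[male], e[!male])$p.value)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)

  # planted case: top-axis edge masculine-positive at n = 400
  cfg1 <- simConfig(nRefAdults = 400, nRois = 20, sexEffectScale = 0.6,
                    seed = 6L)
  geom1 <- generateParcelGeometry(20, 6L)
  ref1 <- generateReferenceCohort(cfg1, geom1)
  ar <- ref1$axis
  top <- order(ar, decreasing = TRUE)[1:2]
  male1 <- ref1$pheno$sex == 1
  diffTop <- mean(ref1$fc[top[1], top[2], male1]) -
    mean(ref1$fc[top[1], top[2], !male1])
  expect_gt(diffTop, 0)
  # generator moments: recovered edge effect close to the configured value
  planted <- cfg1$sexEffectScale *
    (ar[top[1]] + ar[top[2]] +
       2 * cfg1$axisInteraction * ar[top[1]] * ar[top[2]])
  expect_equal(diffTop, planted, tolerance = 0.35)

  expect_identical(generateReferenceCohort(cfg1, geom1)$pheno, ref1$pheno)
  cfgSmall <- tinyConfig()
  cfgSmall$nRefAdults <- 20
  expect_error(generateReferenceCohort(cfgSmall, geom), "rank-deficient")
})

test_that("adolescent cohort realizes the planted linear-Gaussian chain", {
  geom <- generateParcelGeometry(20, 2L)
  # null chain: all paths zero
  cfg0 <- tinyConfig(seed = 2L,
                     pathCoefficients = list(prsToBrain = 0, brainToPhysio = 0,
                                             physioToSymptom = 0, direct = 0))
  a0 <- generateAdolescentCohort(cfg0, geom)
  r0 <- cor(a0$truth$prsz, a0$truth$ylat)
  expect_lt(abs(r0), 3 / sqrt(cfg0$nAdolescents))

  # closed-form path algebra at n = 2000: cor(PRS, symptom) = a*b*c
  cfg1 <- simConfig(nAdolescents = 2000, nRois = 10, seed = 3L)
  geom1 <- generateParcelGeometry(10, 3L)
  a1 <- generateAdolescentCohort(cfg1, geom1)
  implied <- 0.5 * 0.5 * 0.5
  se <- (1 - implied^2) / sqrt(2000)
  expect_lt(abs(cor(a1$truth$prsz, a1$truth$ylat) - implied), 3 * se)
  # the chain is visible in the realized phenotypes too
  chg <- changeScores(a1$pheno["cbcl_anxiety_t2"], a1$pheno["cbcl_anxiety_t3"])
  expect_gt(cor(a1$truth$ylat, chg[[1]]), 0.2)

  a1b <- generateAdolescentCohort(cfg1, geom1)
  expect_identical(a1$pheno, a1b$pheno)
  expect_identical(a1$fcT1, a1b$fcT1)

  cfgBad <- tinyConfig()
  cfgBad$pathCoefficients$direct <- NaN
  expect_error(generateAdolescentCohort(cfgBad, geom), "non-finite")

  # estradiol present only for girls; CBCL non-negative
  expect_true(all(is.na(a0$pheno$estradiol_t2[a0$pheno$sex == 1])))
  expect_true(all(!is.na(a0$pheno$estradiol_t2[a0$pheno$sex == -1])))
  expect_true(all(a0$pheno[grep("^cbcl_", names(a0$pheno))] >= 0))
})

test_that("the time-series route reproduces the matrix-level connectivity", {
  cfgD <- simConfig(nAdolescents = 6, nRois = 16, nFrames = 400,
                    nRuns = 3, seed = 8L)
  cfgT <- cfgD
  cfgT$fcFromTimeSeries <- TRUE
  geom <- generateParcelGeometry(16, 8L)
  viaTs <- generateAdolescentCohort(cfgT, geom)
  # the run-averaged time-series estimate tracks a matrix-level target
  # edge by edge (sampling error ~1/sqrt(frames * runs))
  set.seed(99)
  ar <- neuroSexDiff:::axisScores(cfgD, geom)
  lt <- lower.tri(matrix(0, 16, 16))
  for (s in 1:4) {
    target <- neuroSexDiff:::bilinearFC(0.15 + 0.1 * ar, ar, 0.25)
    recon <- neuroSexDiff:::fcViaTimeSeries(target, 400, 4)
    expect_gt(cor(target[lt], recon[lt]), 0.85)
  }
  # the time-series route goes through the connectivity module: diagonal
  # masked, symmetric
  expect_true(all(is.na(diag(viaTs$fcT1[, , 1]))))
  m <- viaTs$fcT1[, , 1]
  expect_equal(m[lt], t(m)[lt], tolerance = 1e-12)
})

test_that("mortality cohort follows the configured Gompertz hazard", {
  # age-only hazard: death fraction increases across age deciles
  cfg <- simConfig(nMortality = 8000, seed = 4L,
                   gompertz = list(b0 = -6, bAge = 0.09,
                                   bBiomarkers = rep(0, 8), gamma = 0.1,
                                   horizonYears = 10))
  mort <- generateMortalityCohort(cfg)
  dec <- cut(mort$chronological_age, quantile(mort$chronological_age,
                                              0:5 / 5), include.lowest = TRUE)
  frac <- tapply(mort$died, dec, mean)
  expect_true(all(diff(frac) > 0))

  # quadrature oracle: death fraction matches 1 - exp(-integral of hazard)
  for (aBand in list(c(20, 24), c(36, 40))) {
    sel <- mort$chronological_age >= aBand[1] &
      mort$chronological_age <= aBand[2]
    aMid <- mean(mort$chronological_age[sel])
    h <- function(t) exp(-6 + 0.09 * aMid) * exp(0.1 * t)
    expected <- 1 - exp(-integrate(h, 0, 10)$value)
    expect_equal(mean(mort$died[sel]), expected, tolerance = 0.05)
  }

  # gamma -> 0 limit matches the exponential closed form
  cfgE <- simConfig(nMortality = 8000, seed = 9L,
                    gompertz = list(b0 = -2.5, bAge = 0, bBiomarkers = rep(0, 8),
                                    gamma = 1e-8, horizonYears = 10))
  mortE <- generateMortalityCohort(cfgE)
  expect_equal(mean(mortE$died), 1 - exp(-exp(-2.5) * 10), tolerance = 0.02)
  expect_true(all(mortE$follow_up > 0))

  cfgBad <- tinyConfig()
  cfgBad$gompertz$horizonYears <- -1
  expect_error(generateMortalityCohort(cfgBad), "horizon")
})

test_that("polygenic scores are filtered weighted dosage sums", {
  dos <- rbind(c(2, 1, 0), c(0, 0, 0), c(1, 2, 2))
  w <- c(0.1, -0.2, 0.5)
  # keep MAF filter inactive: supply explicit frequencies
  res <- scorePrs(dos, w, maf = c(0.3, 0.3, 0.3))
  expect_equal(res$scores[1], 0.1 * 2 - 0.2 * 1 + 0.5 * 0)
  expect_equal(res$scores[2], 0)
  expect_equal(scorePrs(dos, 2 * w, maf = rep(0.3, 3))$scores,
               2 * res$scores)
  # ambiguous pairs and indels are excluded
  res2 <- scorePrs(dos, w, effectAllele = c("A", "A", "AT"),
                   otherAllele = c("T", "C", "A"), maf = rep(0.3, 3))
  expect_equal(res2$retained, 2L)
  expect_equal(res2$scores, dos[, 2] * w[2])
  # MAF filter
  res3 <- scorePrs(dos, w, maf = c(0.01, 0.3, 0.3))
  expect_false(1L %in% res3$retained)
  expect_error(scorePrs(dos, w[1:2]), "align")
  expect_error(scorePrs(dos, w, maf = rep(0.01, 3)), "empty panel")
})
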