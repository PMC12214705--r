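makeRefFixture <- function(seed = 21L, sexEffectScale = 0.4, n = 120,
                           R = 12) {
  cfg <- simConfig(nRefAdults = n, nRois = R,
                   sexEffectScale = sexEffectScale, seed = seed)
  geom <- generateParcelGeometry(R, seed)
  list(cfg = cfg, geom = geom, ref = generateReferenceCohort(cfg, geom))
}

test_that("template t-statistics match the per-edge regression oracle", {
  set.seed(31)
  n <- 8; R <- 4
  fc <- array(rnorm(R * R * n), c(R, R, n))
  for (s in seq_len(n)) {
    m <- fc[, , s]; m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- NA; fc[, , s] <- m
  }
  ph <- data.frame(sex = rep(c(1, -1), 4), age = rnorm(n))
  tpl <- fitSexDiffTemplate(fc, ph, covariates = "age")
  for (edge in list(c(2, 1), c(4, 3))) {
    y <- fc[edge[1], edge[2], ]
    fit <- summary(lm(y ~ ph$sex + ph$age))
    expect_equal(tstatMatrix(tpl)[edge[1], edge[2]],
                 fit$coefficients["ph$sex", "t value"], tolerance = 1e-10)
  }
  expect_equal(templateDof(tpl), n - 3)

  # exact sign equivariance under sex-code flip
  ph2 <- ph; ph2$sex <- -ph$sex
  tpl2 <- fitSexDiffTemplate(fc, ph2, covariates = "age")
  expect_equal(tstatMatrix(tpl2)[lower.tri(diag(R))],
               -tstatMatrix(tpl)[lower.tri(diag(R))], tolerance = 1e-12)

  phOne <- ph; phOne$sex <- 1
  expect_error(fitSexDiffTemplate(fc, phOne, covariates = "age"),
               "both sexes")
})

test_that("template null calibration: ~5% of |t| exceed the 97.5% quantile", {
  fx <- makeRefFixture(seed = 22L, sexEffectScale = 0.4, n = 80, R = 16)
  ph <- fx$ref$pheno
  set.seed(99)
  ph$sex <- sample(ph$sex)  # break the planted sex link
  tpl <- fitSexDiffTemplate(fx$ref$fc, ph)
  tt <- tstatMatrix(tpl)[lower.tri(diag(16))]
  rate <- mean(abs(tt) > qt(0.975, templateDof(tpl)))
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)  # 120 edges: binomial band around 0.05
})

test_that("regional scoring is a rank statistic with the stated invariances", {
  fx <- makeRefFixture()
  tpl <- fitSexDiffTemplate(fx$ref$fc, fx$ref$pheno)
  tm <- tstatMatrix(tpl)
  R <- nrow(tm)
  # strictly increasing transform of a template row scores rho = 1
  fc <- matrix(rnorm(R * R), R); fc <- (fc + t(fc)) / 2; diag(fc) <- NA
  fc[3, ] <- exp(tm[3, ] / 2); fc[, 3] <- fc[3, ]
  prof <- scoreSexDiff(fc, tpl)
  expect_equal(prof[3], 1)
  fcNeg <- fc
  fcNeg[5, ] <- -tm[5, ]; fcNeg[, 5] <- fcNeg[5, ]
  expect_equal(scoreSexDiff(fcNeg, tpl)[5], -1)
  expect_true(all(abs(prof) <= 1, na.rm = TRUE))

  # 5-ROI toy row against the brute-force rank formula
  fc5 <- matrix(rnorm(25), 5); fc5 <- (fc5 + t(fc5)) / 2; diag(fc5) <- NA
  tm5 <- matrix(rnorm(25), 5); tm5 <- (tm5 + t(tm5)) / 2; diag(tm5) <- NA
  tpl5 <- new("SexDiffTemplate", tstat = tm5, dof = 10,
              covariates = "none")
  p5 <- scoreSexDiff(fc5, tpl5)
  i <- 2
  a <- rank(fc5[i, -i]); b <- rank(tm5[i, -i])
  expect_equal(p5[i], 1 - 6 * sum((a - b)^2) / (4 * (16 - 1)))

  # vectorized cohort scorer agrees with the per-subject path
  stack <- array(rnorm(R * R * 3), c(R, R, 3))
  for (s in 1:3) {
    m <- stack[, , s]; m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- NA; stack[, , s] <- m
  }
  fast <- scoreCohortSexDiff(stack, tpl)
  slow <- t(sapply(1:3, function(s) scoreSexDiff(stack[, , s], tpl)))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("cohort profiles recover the planted axis-aligned differentiation", {
  # under a null generator the cohort-mean profile is ~0 per region
  geom <- generateParcelGeometry(20, 23L)
  cfg0 <- simConfig(nRefAdults = 150, nAdolescents = 150, nRois = 20,
                    sexEffectScale = 0, brainLoadScale = 0, seed = 23L)
  ref0 <- generateReferenceCohort(cfg0, geom)
  tpl0 <- fitSexDiffTemplate(ref0$fc, ref0$pheno)
  adol0 <- generateAdolescentCohort(cfg0, geom)
  prof0 <- scoreCohortSexDiff(adol0$fcT1, tpl0)
  se <- apply(prof0, 2, sd) / sqrt(nrow(prof0))
  expect_true(mean(abs(colMeans(prof0)) < 3 * se) > 0.9)

  # parameter recovery: mean-profile sex contrast associates with the axis
  cfg1 <- simConfig(nRefAdults = 400, nAdolescents = 200, nRois = 100,
                    seed = 24L)
  geom1 <- generateParcelGeometry(100, 24L)
  ref1 <- generateReferenceCohort(cfg1, geom1)
  tpl1 <- fitSexDiffTemplate(ref1$fc, ref1$pheno)
  adol1 <- generateAdolescentCohort(cfg1, geom1)
  prof1 <- scoreCohortSexDiff(adol1$fcT1, tpl1)
  male <- adol1$pheno$sex == 1
  contrast <- colMeans(prof1[male, ]) - colMeans(prof1[!male, ])
  expect_gt(cor(contrast, adol1$truth$axis, method = "spearman"), 0.8)
  expect_gt(mean(contrast), 0)
})

test_that("axis alignment reports Spearman rho with a spin p-value", {
  geom <- generateParcelGeometry(30, 25L)
  spins <- generateSpins(geom, 99, seed = 3L)
  axis <- rank(geom$z)
  res <- alignToAxis(axis, axis, spins)
  expect_equal(res$rho, 1)
  expect_lte(res$pSpin, 0.05)
  resNeg <- alignToAxis(-axis, axis, spins)
  expect_equal(resNeg$rho, -1)
  expect_error(alignToAxis(rep(1, 30), axis, spins), "constant")
  expect_error(alignToAxis(axis[-1], axis[-1], spins), "length|match")
})

test_that("partial-correlation mapping yields one map per measure (13 for the study set)", {
  set.seed(26)
  n <- 80; R <- 10
  profiles <- matrix(rnorm(n * R), n, R)
  confounds <- data.frame(age = rnorm(n), handedness = rbinom(n, 1, 0.1),
                          race = rbinom(n, 1, 0.3),
                          sex = sample(c(-1, 1), n, TRUE),
                          site = sample(c("s1", "s2"), n, TRUE),
                          mean_fd = runif(n))
  cbcl <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(cbcl) <- paste0("cbcl_", 1:9)
  measures <- cbind(cbcl, bmi = rnorm(n), deprivation = rnorm(n),
                    adrenarche = rnorm(n), gonadarche = rnorm(n))
  maps <- mapPartialCorrelations(profiles, measures, confounds)
  expect_equal(ncol(maps), 13)
  expect_equal(nrow(maps), R)

  # a measure (noisily) duplicated from a confound maps to ~0 everywhere
  measures2 <- cbind(measures, dup = confounds$age + 0.01 * rnorm(n))
  maps2 <- mapPartialCorrelations(profiles, measures2, confounds)
  expect_true(all(abs(maps2[, "dup"]) < 3 / sqrt(n)))
  # an exact duplicate is constant after residualization: NA map + warning
  expect_warning(
    mapsDup <- mapPartialCorrelations(profiles,
                                      data.frame(dup = confounds$age),
                                      confounds),
    "constant")
  expect_true(all(is.na(mapsDup[, "dup"])))

  # a planted association at one region carries the map's max |rho|
  target <- rnorm(n)
  profiles3 <- profiles
  profiles3[, 7] <- target + 0.5 * rnorm(n)
  maps3 <- mapPartialCorrelations(profiles3,
                                  data.frame(target = target), confounds)
  expect_equal(unname(which.max(abs(maps3[, "target"]))), 7L)
})
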