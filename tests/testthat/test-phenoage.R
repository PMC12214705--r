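injectModel <- function(b0 = -10, bAge = 0.1, bio = rep(0, 8), gamma = 0.09,
                        horizon = 10, ageOnly = NULL) {
  names(bio) <- paste0("x", seq_along(bio))
  new("GompertzMortalityModel", intercept = b0, ageCoef = bAge,
      biomarkerCoef = bio, gamma = gamma, horizon = horizon,
      ageOnly = ageOnly %||% list(intercept = b0, ageCoef = bAge,
                                  gamma = gamma),
      logLik = NA_real_, n = 0, nEvents = 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the likelihood matches a quadrature oracle on a tiny dataset", {
  set.seed(41)
  X <- cbind(1, age = c(25, 30, 35, 28, 33, 38))
  time <- c(2.3, 9.9, 4.1, 10, 7.2, 1.1)
  died <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  par <- c(-4.2, 0.05, log(0.12))
  # oracle: survival via numerical integration of the hazard; density as
  # hazard times survival
  ll <- 0
  for (i in seq_len(6)) {
    h <- function(t) exp(sum(X[i, ] * par[1:2])) * exp(0.12 * t)
    S <- exp(-integrate(h, 0, time[i])$value)
    ll <- ll + log(S) + if (died[i]) log(h(time[i])) else 0
  }
  expect_equal(-neuroSexDiff:::gompertzNll(par, X, time, died), ll,
               tolerance = 1e-6)
})

test_that("predicted mortality follows the closed-form Gompertz risk", {
  m <- injectModel(b0 = -10, bAge = 0.1, bio = c(0.5, -0.2, rep(0, 6)),
                   gamma = 0.09, horizon = 10)
  bio <- matrix(c(1.2, 0.4, rep(0, 6)), 1,
                dimnames = list(NULL, paste0("x", 1:8)))
  lp <- -10 + 0.1 * 30 + 0.5 * 1.2 - 0.2 * 0.4
  hand <- 1 - exp(-exp(lp) * (exp(0.09 * 10) - 1) / 0.09)
  expect_equal(predictMortality(m, 30, bio), hand, tolerance = 1e-12)

  # monotone in a positively weighted biomarker; vanishing risk in the limit
  bio2 <- bio; bio2[1] <- 2
  expect_gt(predictMortality(m, 30, bio2), predictMortality(m, 30, bio))
  mLow <- injectModel(b0 = -500)
  expect_lt(predictMortality(mLow, 30,
                             matrix(0, 1, 8,
                                    dimnames = list(NULL, paste0("x", 1:8)))),
            1e-100)
  expect_error(predictMortality(m, Inf, bio), "non-finite")
})

test_that("inversion identities hold exactly", {
  # all biomarker coefficients zero and submodel equal to the age part:
  # biological age equals chronological age
  m0 <- injectModel(bio = rep(0, 8))
  bio0 <- matrix(rnorm(8 * 5), 5, dimnames = list(NULL, paste0("x", 1:8)))
  ages <- c(21, 27.5, 30, 34.2, 39)
  expect_equal(phenoAge(m0, ages, bio0), ages, tolerance = 1e-8)
  risk <- predictMortality(m0, ages, bio0)
  expect_equal(invertToPhenoAge(m0, risk), ages, tolerance = 1e-8)

  # shared-gamma construction: phenoage = age + Delta / b_age exactly
  m1 <- injectModel(bio = c(0.3, -0.4, rep(0.1, 6)))
  delta <- drop(bio0 %*% m1@biomarkerCoef)
  expect_equal(phenoAge(m1, ages, bio0), ages + delta / m1@ageCoef,
               tolerance = 1e-8)

  # risk-monotone implies phenoage-monotone
  rs <- c(0.05, 0.1, 0.4, 0.9)
  expect_true(all(diff(invertToPhenoAge(m1, rs)) > 0))
  expect_error(invertToPhenoAge(m1, 1.2), "risk")
})

test_that("the fitted model agrees with an independent Gompertz PH fit", {
  cfg <- simConfig(nMortality = 1500, seed = 42L)
  mort <- generateMortalityCohort(cfg)
  mm <- fitMortalityModel(mort, horizon = cfg$gompertz$horizonYears)
  bm <- neuroSexDiff:::biomarkerReference()
  fs <- flexsurv::flexsurvreg(
    survival::Surv(follow_up, died) ~ chronological_age + mcv + rbc + rdw +
      wbc + lymphocyte_pct + monocyte_pct + hba1c + total_cholesterol,
    data = mort, dist = "gompertz")
  co <- coef(fs)
  expect_equal(mm@gamma, unname(co["shape"]), tolerance = 1e-2)
  expect_equal(mm@intercept, unname(co["rate"]), tolerance = 1e-2)
  expect_equal(unname(mm@biomarkerCoef),
               unname(co[bm$name]), tolerance = 1e-2)
  expect_equal(mm@ageCoef, unname(co["chronological_age"]), tolerance = 1e-2)
})

test_that("pure-noise biomarkers get coefficients within 3 SE of zero", {
  cfg <- simConfig(nMortality = 2000, seed = 43L,
                   gompertz = list(b0 = -4.5, bAge = 0.08,
                                   bBiomarkers = rep(0, 8), gamma = 0.15,
                                   horizonYears = 10))
  mort <- generateMortalityCohort(cfg)
  mm <- fitMortalityModel(mort, horizon = 10)
  X <- cbind(1, mort$chronological_age,
             as.matrix(mort[neuroSexDiff:::biomarkerReference()$name]))
  par <- c(mm@intercept, mm@ageCoef, mm@biomarkerCoef, log(mm@gamma))
  H <- optimHess(par, neuroSexDiff:::gompertzNll,
                 neuroSexDiff:::gompertzGrad, X = X,
                 time = mort$follow_up, died = mort$died)
  se <- sqrt(diag(solve(H)))[3:10]
  expect_true(all(abs(mm@biomarkerCoef) < 3 * se))
  expect_error(fitMortalityModel(mort[!mort$died, ][1:100, ]), "events")
})

test_that("acceleration is the age- and sex-adjusted residual", {
  set.seed(44)
  n <- 12
  age <- runif(n, 20, 40)
  sex <- rep(c(1, -1), 6)
  expect_equal(ageAcceleration(age, age, sex), rep(0, n), tolerance = 1e-10)
  pa <- age + rnorm(n, sd = 3)
  acc <- ageAcceleration(pa, age, sex)
  expect_lt(abs(sum(acc * (age - mean(age)))), 1e-8)
  expect_lt(abs(sum(acc * (sex - mean(sex)))), 1e-8)
  expect_lt(abs(mean(acc)), 1e-10)
  fit <- lm(pa ~ age + sex)
  expect_equal(acc, unname(residuals(fit)), tolerance = 1e-10)
  expect_error(ageAcceleration(pa, rep(30, n), sex), "constant age")
  expect_error(ageAcceleration(pa[1:5], age[1:5], sex[1:5]), "10 subjects")
})
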