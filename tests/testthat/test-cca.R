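# Independent oracle: canonical correlations as the square roots of the
# eigenvalues of solve(Sxx) Sxy solve(Syy) Syx on standardized data.
ccaEigenOracle <- function(X, Y) {
  Xs <- scale(X)
  Ys <- scale(Y)
  Sxx <- cov(Xs); Syy <- cov(Ys); Sxy <- cov(Xs, Ys)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sqrt(pmax(0, sort(Re(eigen(M)$values), decreasing = TRUE)))
}

test_that("fitCca matches the generalized-eigenproblem oracle", {
  set.seed(61)
  for (rep in 1:25) {
    p <- sample(2:4, 1); q <- sample(2:4, 1); n <- 30
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * q), n)
    fit <- fitCca(X, Y)
    expect_equal(canonicalCorrelations(fit),
                 ccaEigenOracle(X, Y)[seq_len(min(p, q))],
                 tolerance = 1e-8)
  }
  # a perfectly shared single column gives canonical correlation 1
  x <- rnorm(40)
  expect_equal(canonicalCorrelations(fitCca(cbind(x), cbind(x))), 1,
               tolerance = 1e-10)
  # independent sets at large n give a near-zero correlation
  set.seed(62)
  expect_lt(canonicalCorrelations(
    fitCca(cbind(rnorm(10000)), cbind(rnorm(10000)))), 0.05)
  expect_error(fitCca(cbind(rep(1, 20), rnorm(20)), cbind(rnorm(20))),
               "constant column")
})

test_that("projection re-applies training preprocessing without refitting", {
  set.seed(63)
  X <- matrix(rnorm(50 * 3), 50)
  Y <- matrix(rnorm(50 * 2), 50)
  fit <- fitCca(X, Y)
  tr <- projectVariate(fit, X)
  # idempotence: projecting the training data reproduces training variates
  expect_equal(cor(tr[, 1], projectVariate(fit, X)[, 1]), 1,
               tolerance = 1e-10)
  expect_equal(var(tr[, 1]), 1, tolerance = 1e-8)
  dup <- projectVariate(fit, X[c(1, 1, 5), ])
  expect_equal(dup[1, ], dup[2, ], tolerance = 1e-12)
  # hand matrix product with injected weights
  W <- matrix(c(1, 0, 0.5, -1, 2, 0), 3, 2)
  inj <- new("CcaModel", xWeights = W, yWeights = W, cors = c(0.9, 0.5),
             xCenter = rep(0, 3), xScale = rep(1, 3),
             yCenter = rep(0, 3), yScale = rep(1, 3))
  X3 <- matrix(c(1, 2, 3, 0, -1, 1, 2, 0, 1), 3, byrow = TRUE)
  expect_equal(projectVariate(inj, X3), X3 %*% W)
  expect_error(projectVariate(fit, X[, 1:2]), "column count")
})

test_that("cross-validated CCA recovers a planted latent and stays null-calibrated", {
  set.seed(64)
  n <- 500
  z <- rnorm(n)
  X <- 0.7 * z + matrix(rnorm(n * 3), n) * 1  # true canonical r = 0.5
  X <- cbind(sqrt(0.5) * z + sqrt(0.5) * rnorm(n), matrix(rnorm(n * 2), n))
  Y <- cbind(sqrt(0.5) * z + sqrt(0.5) * rnorm(n), matrix(rnorm(n * 2), n))
  res <- crossValidateCca(X, Y, k = 10, seed = 7L)
  expect_gt(rCV(res), 0.35)
  expect_lt(rCV(res), 0.6)
  res2 <- crossValidateCca(X, Y, k = 10, seed = 7L)
  expect_identical(res@folds, res2@folds)
  expect_equal(rCV(res), rCV(res2))

  # independent sets: r_CV centered near zero over replicates
  set.seed(65)
  rs <- replicate(100, {
    rCV(crossValidateCca(matrix(rnorm(120), 60), matrix(rnorm(120), 60),
                         k = 10, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(crossValidateCca(matrix(rnorm(24), 12),
                                matrix(rnorm(24), 12), k = 10), "n/3")
})

test_that("permutation p-values follow the +1 formula and two-sided symmetry", {
  set.seed(66)
  n <- 60
  z <- rnorm(n)
  X <- cbind(z + 0.2 * rnorm(n))
  Y <- cbind(z + 0.2 * rnorm(n))
  res <- crossValidateCca(X, Y, k = 6, seed = 3L)
  resP <- ccaPermutationPvalue(res, X, Y, k = 6, nPerm = 999, seed = 5L)
  expect_equal(permutationP(resP), 1 / 1000)  # observed r beats all nulls
  # two-sided: jointly negating one set leaves p unchanged
  resN <- crossValidateCca(X, -Y, k = 6, seed = 3L)
  resNP <- ccaPermutationPvalue(resN, X, -Y, k = 6, nPerm = 999, seed = 5L)
  expect_equal(permutationP(resNP), permutationP(resP))
  expect_warning(ccaPermutationPvalue(res, X, Y, k = 6, nPerm = 50,
                                      seed = 5L), "unstable")
})

test_that("bootstrap loadings bracket the truth and respect ordering", {
  set.seed(67)
  n <- 150
  z <- rnorm(n)
  X <- cbind(strong = z + 0.05 * rnorm(n), noise = rnorm(n))
  Y <- cbind(partner = z + 0.05 * rnorm(n))
  res <- crossValidateCca(X, Y, k = 10, seed = 2L)
  res <- bootstrapLoadings(res, nBoot = 400, seed = 9L)
  tab <- loadingTable(res)
  expect_true(all(tab$lo <= tab$estimate & tab$estimate <= tab$hi))
  strong <- tab[tab$variable == "strong", ]
  expect_gt(abs(strong$estimate), 0.95)
  expect_true(strong$robust)
  noiseRow <- tab[tab$variable == "noise", ]
  expect_false(noiseRow$robust)

  # a variable independent of the variate straddles zero in most repeats
  straddle <- replicate(30, {
    Xr <- cbind(z + 0.2 * rnorm(n), indep = rnorm(n))
    r <- bootstrapLoadings(crossValidateCca(Xr, Y, k = 5,
                                            seed = sample.int(1e6, 1)),
                           nBoot = 200, level = 0.99,
                           seed = sample.int(1e6, 1))
    tb <- loadingTable(r)
    tb$lo[2] < 0 & tb$hi[2] > 0
  })
  expect_gte(mean(straddle), 0.9)
})

test_that("standardized contributions reduce to correlations for orthonormal predictors", {
  set.seed(68)
  n <- 200
  P <- qr.Q(qr(matrix(rnorm(n * 3), n))) * sqrt(n - 1)
  v <- P %*% c(0.5, -0.3, 0.1) + rnorm(n, sd = 0.3)
  tab <- standardizedContributions(v, as.data.frame(P))
  expect_equal(tab$estimate, drop(cor(P, (v - mean(v)) / sd(v))),
               tolerance = 0.02)
  # predictor duplicated among the controls has no unique contribution
  expect_warning(
    tab2 <- standardizedContributions(v, data.frame(p1 = P[, 1]),
                                      controls = data.frame(dup = P[, 1])),
    "captured")
  expect_equal(tab2$estimate[1], 0)
  # 6-row toy against the normal equations
  v6 <- c(0.2, 1.5, -0.8, 0.4, 2.0, -1.1)
  p6 <- data.frame(q = c(1, 0, 2, -1, 1, 0.5))
  tab6 <- standardizedContributions(v6, p6)
  z6 <- scale(v6)[, 1]
  q6 <- scale(p6$q)[, 1]
  expect_equal(tab6$estimate, unname(olsOracle(cbind(q6), z6)[2]),
               tolerance = 1e-10)
})
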