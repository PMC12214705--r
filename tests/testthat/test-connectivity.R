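test_that("framewise displacement follows the backward-difference formula", {
  zero <- matrix(0, 10, 6)
  expect_equal(framewiseDisplacement(zero)$fd, rep(0, 10))

  m <- matrix(0, 2, 6)
  m[2, 1:3] <- c(0.1, 0.2, 0.2)
  m[2, 4] <- 0.002
  fd <- framewiseDisplacement(m)
  expect_equal(fd$fd[2], 0.5 + 50 * 0.002)  # hand computation: 0.6 mm
  expect_equal(fd$fd[1], 0)

  set.seed(1)
  m2 <- matrix(rnorm(60, sd = 0.05), 10, 6)
  expect_equal(framewiseDisplacement(2 * m2)$fd,
               2 * framewiseDisplacement(m2)$fd)
  expect_error(framewiseDisplacement(m2[, 1:5]), "6 columns")
  expect_error(framewiseDisplacement(m2[1, , drop = FALSE]), "2 frames")
})

test_that("respiratory band-stop filter attenuates in-band, preserves out-of-band", {
  tr <- 0.8
  n <- 400
  t <- (seq_len(n) - 1) * tr
  amp <- function(x, f) {
    # FFT oracle: amplitude at the bin nearest frequency f
    sp <- Mod(fft(x - mean(x))) / n * 2
    freqs <- (seq_len(n) - 1) / (n * tr)
    sp[which.min(abs(freqs - f))]
  }
  inBand <- sin(2 * pi * 0.37 * t)
  m <- matrix(rep(inBand, 6), n, 6)
  out <- filterMotionRegressors(m, trSeconds = tr)
  expect_lt(amp(out[, 1], 0.37), 0.10 * amp(inBand, 0.37))

  lowFreq <- sin(2 * pi * 0.05 * t)
  out2 <- filterMotionRegressors(matrix(rep(lowFreq, 6), n, 6),
                                 trSeconds = tr)
  expect_equal(amp(out2[, 1], 0.05), amp(lowFreq, 0.05), tolerance = 0.05)

  const <- matrix(3.7, n, 6)
  expect_equal(filterMotionRegressors(const, trSeconds = tr), const,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(filterMotionRegressors(m, bandHz = c(0.31, 0.7),
                                      trSeconds = tr), "Nyquist")
})

test_that("motion expansion yields exactly the 24-regressor set", {
  set.seed(2)
  m <- matrix(rnorm(60), 10, 6)
  out <- expandMotionTerms(m)
  expect_equal(ncol(out), 24)
  expect_true(all(out[, 13:24] >= 0))
  constant <- matrix(1.5, 10, 6)
  expect_equal(expandMotionTerms(constant)[, 7:12],
               matrix(0, 10, 6), ignore_attr = TRUE)
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  set.seed(3)
  nuis <- matrix(rnorm(100 * 3), 100, 3)
  ts1 <- nuis[, 2, drop = FALSE]
  expect_lt(max(abs(regressNuisance(ts1, nuis))), 1e-10)

  # orthogonal nuisance: time series unchanged
  x <- rnorm(100)
  xc <- x - mean(x)
  orth <- qr.resid(qr(cbind(1, xc)), matrix(rnorm(200), 100, 2))
  expect_equal(regressNuisance(matrix(xc), orth), matrix(xc),
               tolerance = 1e-10, ignore_attr = TRUE)

  # 5-frame toy against the normal-equations oracle
  ts5 <- matrix(c(1.2, -0.3, 0.8, 2.1, -1.5))
  z5 <- matrix(c(0.5, 1.0, -1.0, 0.2, 0.7))
  beta <- olsOracle(z5, ts5)
  expect_equal(regressNuisance(ts5, z5),
               ts5 - cbind(1, z5) %*% beta, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(regressNuisance(ts5, z5[1:4, , drop = FALSE]), "frame count")
  expect_warning(regressNuisance(ts5, cbind(z5, z5)), "rank-deficient")
})

test_that("Fisher-z connectivity clips, masks the diagonal, and averages", {
  set.seed(4)
  x <- rnorm(50)
  tsM <- cbind(x, x, rnorm(50))
  expect_warning(z <- computeFc(cbind(tsM, rep(1, 50))), "zero-variance")
  expect_true(all(is.na(z[4, ])))
  expect_equal(z[1, 2], atanh(1 - 1e-7))  # degenerate clip rule
  expect_true(all(is.na(diag(z))))

  p <- exactCorPair(60, 0.5, seed = 5L)
  z5 <- computeFc(cbind(p, rnorm(60)))
  expect_equal(round(z5[1, 2], 4), 0.5493)  # Fisher z at r = 0.5

  tt <- seq_len(1000)
  orth <- cbind(sin(2 * pi * tt / 100), cos(2 * pi * tt / 100))
  expect_lt(abs(computeFc(orth)[1, 2]), 0.05)
  expect_error(computeFc(orth[1:10, ]), "20 frames")

  m1 <- computeFc(matrix(rnorm(80), 40, 2))
  expect_equal(averageFc(list(m1, m1)), m1)
  expect_equal(averageFc(list(m1, -m1))[1, 2], 0)
  a <- matrix(c(NA, 1, 2, 1, NA, 3, 2, 3, NA), 3)
  b <- a + 1; diag(b) <- NA
  cM <- a - 2; diag(cM) <- NA
  expect_equal(averageFc(list(a, b, cM))[1, 2], mean(c(1, 2, -1)))
  expect_error(averageFc(list()), "empty")
})

test_that("QC-FC diagnostics detect planted motion artifacts and stay null-calibrated", {
  set.seed(6)
  R <- 12; n <- 200
  fd <- exp(rnorm(n, log(0.12), 0.3))
  stack <- array(rnorm(R * R * n, sd = 0.3), c(R, R, n))
  for (s in seq_len(n)) {
    m <- stack[, , s]; m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- NA; stack[, , s] <- m
  }
  geom <- generateParcelGeometry(R, 1L)
  nullRes <- qcFc(stack, fd, geom)
  expect_lt(abs(nullRes$medianAbs - median(abs(nullRes$edgeCor))), 1e-12)
  expect_lt(nullRes$medianAbs, 0.2)
  expect_lt(abs(median(nullRes$edgeCor)), 0.02)
  # distance dependence statistic consistent with its permutation null
  expect_gt(mean(abs(nullRes$nullRho) >= abs(nullRes$distanceRho)), 0.01)

  # plant one edge proportional to FD
  stack[1, 2, ] <- stack[2, 1, ] <- 5 * fd
  planted <- qcFc(stack, fd, geom)
  expect_gt(planted$edgeCor[1], 0.9)  # edge (2,1) is the first lower-tri edge
  expect_error(qcFc(stack, rep(0.1, n)), "constant")
  expect_error(qcFc(stack[, , 1:5], fd[1:5]), "10 subjects")
})

test_that("motion exclusion applies the three strict criteria", {
  sm <- data.frame(
    subject = c("a", "b", "c", "d"),
    meanFd = c(0.25, 0.10, 0.20, NA),
    fracBelow = c(0.95, 0.85, 0.90, 0.9),
    maxMotion = c(1, 2, 1, 1))
  res <- applyMotionExclusion(sm)
  expect_identical(res$retained, "b")
  expect_match(res$log$reason[1], "mean FD")
  expect_match(res$log$reason[3], "mean FD")     # exactly 0.20 is excluded
  expect_match(res$log$reason[4], "missing")
  sm2 <- data.frame(subject = "e", meanFd = 0.1, fracBelow = 0.85,
                    maxMotion = 6)
  expect_length(applyMotionExclusion(sm2)$retained, 0)
})
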