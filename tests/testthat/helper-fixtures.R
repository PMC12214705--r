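# Small shared fixtures, built in code.

tinyConfig <- function(seed = 11L, ...) {
  simConfig(nRefAdults = 120, nAdolescents = 100, nRois = 20,
            nMortality = 1200, seed = seed, ...)
}

# Exact-correlation pair: returns a 2-column matrix whose sample Pearson
# correlation is exactly `r` (Gram-Schmidt construction).
exactCorPair <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- residuals(lm(e ~ x))
  e <- e / sd(e)
  cbind(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Brute-force OLS via normal equations (independent oracle).
olsOracle <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)
}
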