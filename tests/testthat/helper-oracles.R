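## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the quadrature oracle integrates the conjugate
## regression numerically, and the OLS oracle recomputes the t-test from
## textbook formulas.

## 2-D numerical integration (log-sigma2 grid x effect grid) of the
## single-effect-column marginal likelihood.
quadrature_logml <- function(w, x, phi2, kappa = 0.001, lambda = 0.001) {
  d <- phi2 / var(x)
  a0 <- kappa / 2
  b0 <- kappa * lambda / 2
  n <- length(w)
  ls2 <- seq(log(1e-6), log(500), length.out = 2000)
  s2 <- exp(ls2)
  dls <- ls2[2] - ls2[1]
  b <- seq(-30, 30, length.out = 6001)
  db <- b[2] - b[1]
  ## residual sum of squares at each effect value (vectorized)
  rs2 <- colSums((matrix(w, n, length(b)) - outer(x, b))^2)
  tot <- 0
  for (s in s2) {
    ll <- -(n / 2) * log(2 * pi * s) - rs2 / (2 * s) +
      dnorm(b, 0, sqrt(s * d), log = TRUE)
    inner <- sum(exp(ll)) * db
    dens <- exp(a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s) - b0 / s)
    tot <- tot + inner * dens * s * dls
  }
  log(tot)
}

## Textbook OLS t-test of the last column of the design.
ols_oracle_p <- function(y, X) {
  fit <- lm(y ~ X - 1)
  summary(fit)$coefficients[ncol(X), 4]
}

## Simulate one triplet under a named structure (unit-variance components).
sim_triplet <- function(n, model = c("forward", "reactive", "independence",
                                     "null"),
                        pve_a = 0.3, pve_b = 0.3, maf = 0.5) {
  model <- match.arg(model)
  x <- rbinom(n, 2, maf)
  xc <- x - 1
  vx <- 2 * maf * (1 - maf)
  a <- sqrt(pve_a / vx)
  b <- sqrt(pve_b)
  if (model == "forward") {
    m <- a * xc + rnorm(n, 0, sqrt(1 - pve_a))
    y <- b * m + rnorm(n, 0, sqrt(1 - pve_b))
  } else if (model == "reactive") {
    y <- a * xc + rnorm(n, 0, sqrt(1 - pve_a))
    m <- b * y + rnorm(n, 0, sqrt(1 - pve_b))
  } else if (model == "independence") {
    m <- a * xc + rnorm(n, 0, sqrt(1 - pve_a))
    y <- a * xc + rnorm(n, 0, sqrt(1 - pve_a))
  } else {
    m <- rnorm(n)
    y <- rnorm(n)
  }
  list(x = x, m = m, y = y)
}
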