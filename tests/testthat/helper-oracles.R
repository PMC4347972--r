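suppressPackageStartupMessages({
  library(GenomicRanges)
})

## Direct-formula ZINB pmf via log-gamma, independent of the package's
## stats::dnbinom route.
refZinbPmf <- function(x, r, p, beta) {
  nb <- exp(lgamma(r + x) - lgamma(r) - lgamma(x + 1) +
              r * log(p) + x * log(1 - p))
  beta * (x == 0) + (1 - beta) * nb
}

## Brute-force forward-backward by exhaustive enumeration of all K^T state
## paths; tractable for K <= 4, T <= 8.
enumPosterior <- function(logE, A, init) {
  Tn <- nrow(logE); K <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  np <- nrow(paths)
  lp <- log(init)[paths[, 1]] + logE[cbind(rep(1L, np), paths[, 1])]
  if (Tn > 1L) for (t in 2:Tn)
    lp <- lp + log(A)[cbind(paths[, t - 1L], paths[, t])] +
      logE[cbind(rep(t, np), paths[, t])]
  M <- max(lp)
  loglik <- M + log(sum(exp(lp - M)))
  w <- exp(lp - loglik)
  gamma <- vapply(seq_len(K), function(k)
    vapply(seq_len(Tn), function(t) sum(w[paths[, t] == k]), numeric(1)),
    numeric(Tn))
  list(gamma = matrix(gamma, nrow = Tn), loglik = loglik)
}

randomStochastic <- function(K) {
  m <- matrix(runif(K * K, 0.05, 1), K)
  m / rowSums(m)
}

randomHmmInstance <- function(K, Tn) {
  p <- runif(K, 0.05, 1)
  list(logE = matrix(log(runif(Tn * K, 0.01, 1)), Tn, K),
       A = randomStochastic(K), init = p / sum(p))
}

## Wrap a fixed log-emission matrix as an HmmModel whose "observations" are
## row indices into the matrix.
matrixHmm <- function(logE, A, init) {
  K <- ncol(logE)
  HmmModel(A, lapply(seq_len(K), function(k) {
    force(k)
    function(o) logE[o, k]
  }), initial = init)
}

## Seeded draw from a two-component ZINB mixture.
genMixtureCounts <- function(n, alpha, theta0, theta1, seed) {
  set.seed(seed)
  fromFirst <- runif(n) < alpha
  x <- integer(n)
  x[fromFirst] <- rzinb(sum(fromFirst), theta0)
  x[!fromFirst] <- rzinb(sum(!fromFirst), theta1)
  x
}

## Midpoint-rule quadrature of the bivariate standard normal density with
## correlation rho over a finite rectangle.
midpointRectProb <- function(lx, hx, ly, hy, rho, n = 400) {
  gx <- lx + (seq_len(n) - 0.5) * (hx - lx) / n
  gy <- ly + (seq_len(n) - 0.5) * (hy - ly) / n
  dens <- outer(gx, gy, function(a, b)
    exp(-(a^2 + b^2 - 2 * rho * a * b) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2)))
  sum(dens) * (hx - lx) * (hy - ly) / n^2
}

## Reference parameter sets used across distribution tests.
testTheta <- function() list(
  ZinbParams(2.5, 0.3, 0.1),
  ZinbParams(1, 0.5, 0),
  ZinbParams(4, 0.08, 0),
  ZinbParams(1.5, 0.6, 0.3))
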