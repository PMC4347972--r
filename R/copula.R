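## CDF values are clipped into [eps, 1-eps] before the inverse-normal so
## probability-integral-transform scores stay finite.
.PIT_EPS <- 1e-12

#' Probability integral transform to standard-normal scores
#'
#' Maps a count through its ZINB marginal CDF and the standard-normal
#' quantile function, \eqn{z = \Phi^{-1}(F(x))}. CDF values are clipped
#' into \eqn{[10^{-12}, 1-10^{-12}]} so scores are always finite.
#'
#' @param x integer counts (values below 0 give the clipped lower bound).
#' @param marginal a \code{\linkS4class{ZinbParams}} marginal.
#' @return standard-normal scores.
#' @export
pitTransform <- function(x, marginal) {
  u <- pmin(pmax(pzinb(x, marginal), .PIT_EPS), 1 - .PIT_EPS)
  stats::qnorm(u)
}

#' Construct a copula emission component
#'
#' @param a,b 0/1 modification indicators for samples A and B.
#' @param marginalX,marginalY ZINB marginals of the two samples in their
#'   respective states.
#' @param sigma 2 x 2 covariance of the transformed pair.
#' @param nSupport number of high-confidence bins behind the estimate.
#' @return a \code{\linkS4class{CopulaComponent}}.
#' @export
CopulaComponent <- function(a, b, marginalX, marginalY, sigma = diag(2),
                            nSupport = 0L) {
  new("CopulaComponent", a = as.integer(a), b = as.integer(b),
      marginalX = marginalX, marginalY = marginalY, sigma = sigma,
      nSupport = as.integer(nSupport))
}

#' Construct a bivariate copula mixture
#'
#' @param components list of four \code{\linkS4class{CopulaComponent}}s in
#'   state order \code{"00"}, \code{"11"}, \code{"10"}, \code{"01"}.
#' @param gammaAb four mixing weights summing to 1 (same order).
#' @return a \code{\linkS4class{BivariateMixture}}.
#' @export
BivariateMixture <- function(components, gammaAb = rep(0.25, 4)) {
  names(components) <- c("00", "11", "10", "01")
  gammaAb <- stats::setNames(as.numeric(gammaAb), names(components))
  new("BivariateMixture", components = components, gammaAb = gammaAb)
}

## Rectangle bounds of a count under its marginal: the bivariate pmf is the
## bivariate-normal measure of [qnorm(F(x-1)), qnorm(F(x))] per dimension,
## with F(-1) = 0 mapping to a -Inf lower bound.
.pitBounds <- function(x, marginal) {
  hi <- pitTransform(x, marginal)
  lo <- ifelse(x <= 0, -Inf, pitTransform(x - 1, marginal))
  cbind(lo, hi)
}

#' Bivariate copula log pmf
#'
#' Log probability \eqn{\log P(X = x, Y = y)} of a
#' \code{\linkS4class{CopulaComponent}}: the bivariate-normal measure of the
#' rectangle between consecutive transformed CDF values,
#' \deqn{P(X=x,Y=y) = \int_{\Phi^{-1}(F_x(x-1))}^{\Phi^{-1}(F_x(x))}
#'   \int_{\Phi^{-1}(F_y(y-1))}^{\Phi^{-1}(F_y(y))}
#'   \phi_\Sigma(z_x,z_y)\, dz_x\, dz_y,}
#' evaluated with an established bivariate-normal algorithm
#' (\code{\link[mvtnorm]{pmvnorm}}, Genz). Since the transformed margins
#' are standard normal by construction, the stored covariance is rescaled
#' to a correlation matrix before evaluation. Probabilities are floored at
#' \code{1e-300} before the log.
#'
#' @param x,y non-negative integer counts (vectors of equal length are
#'   evaluated pairwise).
#' @param comp a \code{\linkS4class{CopulaComponent}}.
#' @return log probabilities, all \code{<= 0}.
#' @export
bivariateLogPmf <- function(x, y, comp) {
  stopifnot(is(comp, "CopulaComponent"))
  if (any(x < 0) || any(y < 0)) stop("'x' and 'y' must be non-negative")
  rho <- copulaCorrelation(comp)
  corr <- matrix(c(1, rho, rho, 1), 2, 2)
  bx <- .pitBounds(x, comp@marginalX)
  by <- .pitBounds(y, comp@marginalY)
  p <- vapply(seq_along(x), function(i) {
    lx <- bx[i, 1]; hx <- bx[i, 2]
    ly <- by[i, 1]; hy <- by[i, 2]
    ## canonical dimension order: the Gaussian is exchangeable under a joint
    ## swap of both coordinates, and a fixed order makes f((x,y); rho) and
    ## the sample-swapped f((y,x); rho) bitwise identical
    if (lx > ly || (lx == ly && hx > hy)) {
      tmp <- lx; lx <- ly; ly <- tmp
      tmp <- hx; hx <- hy; hy <- tmp
    }
    as.numeric(mvtnorm::pmvnorm(lower = c(lx, ly), upper = c(hx, hy),
                                corr = corr))
  }, numeric(1))
  log(pmax(pmin(p, 1), .PMF_FLOOR))
}

## Memoizing per-component emission closure: counts are small integers
## repeated genome-wide, so each distinct (x, y) pair is evaluated once per
## component over the whole run. Cache identity == closure identity ==
## component identity.
.copulaEmissionFun <- function(comp) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(o) {
    key <- paste(o[, 1], o[, 2])
    miss <- !vapply(key, exists, TRUE, envir = cache, inherits = FALSE,
                    USE.NAMES = FALSE)
    if (any(miss)) {
      newKey <- key[miss]
      firstNew <- !duplicated(newKey)
      vals <- bivariateLogPmf(o[miss, 1][firstNew], o[miss, 2][firstNew],
                              comp)
      mapply(function(k, v) assign(k, v, envir = cache),
             newKey[firstNew], vals)
    }
    vapply(key, get, numeric(1), envir = cache, USE.NAMES = FALSE)
  }
}

#' Estimate the four copula components from high-confidence calls
#'
#' Builds the four-component bivariate emission mixture of the differential
#' HMM. For every state combination (a, b), bins whose univariate posterior
#' supports state a in sample A and state b in sample B with probability
#' above \code{confidence} form the component's support; the counts of
#' these bins are probability-integral-transformed with the corresponding
#' ZINB marginals, and the component covariance is the sample covariance of
#' the transformed pairs. Components with fewer than \code{minSupport}
#' supporting bins fall back to the identity covariance (with a warning).
#' Mixing weights are the support fractions; they are diagnostic only, as
#' the HMM transition structure supersedes them.
#'
#' @param trackA,trackB \code{\linkS4class{BinnedTrack}}s over identical
#'   bins.
#' @param postA,postB univariate \code{\linkS4class{PosteriorTrack}}s of
#'   the two samples (two states: unmodified, modified).
#' @param mixA,mixB fitted \code{\linkS4class{UnivariateMixture}}s.
#' @param confidence posterior cutoff for high-confidence support
#'   (default 0.9).
#' @param minSupport minimum bins per component (default 50).
#' @return a \code{\linkS4class{BivariateMixture}}.
#' @export
estimateComponentCovariance <- function(trackA, trackB, postA, postB,
                                        mixA, mixB, confidence = 0.9,
                                        minSupport = 50L) {
  if (length(trackA) != length(trackB))
    stop("tracks must share identical bins")
  if (confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie in (0, 1)")
  x <- counts(trackA); y <- counts(trackB)
  gA <- posteriorMatrix(postA); gB <- posteriorMatrix(postB)
  stopifnot(nrow(gA) == length(x), nrow(gB) == length(y))

  stateOrder <- list("00" = c(0L, 0L), "11" = c(1L, 1L),
                     "10" = c(1L, 0L), "01" = c(0L, 1L))
  comps <- vector("list", 4L)
  nSel <- integer(4L)
  for (k in seq_along(stateOrder)) {
    ab <- stateOrder[[k]]
    a <- ab[1]; b <- ab[2]
    thA <- component(mixA, a)
    thB <- component(mixB, b)
    sel <- gA[, a + 1L] > confidence & gB[, b + 1L] > confidence
    n <- sum(sel)
    nSel[k] <- n
    sigma <- diag(2)
    if (n >= minSupport) {
      z <- cbind(pitTransform(x[sel], thA), pitTransform(y[sel], thB))
      s <- stats::cov(z)
      sdx <- sqrt(s[1, 1]); sdy <- sqrt(s[2, 2])
      if (is.finite(sdx) && is.finite(sdy) && sdx > 1e-6 && sdy > 1e-6) {
        rho <- s[1, 2] / (sdx * sdy)
        ## perfectly correlated supports (e.g. a track against itself)
        ## would make sigma singular; cap |rho| just inside the unit ball
        rho <- sign(rho) * min(abs(rho), 0.999)
        sigma <- matrix(c(sdx^2, rho * sdx * sdy,
                          rho * sdx * sdy, sdy^2), 2, 2)
      } else {
        warning(sprintf(
          "component (%d,%d): degenerate transformed counts; identity covariance used",
          a, b))
      }
    } else {
      warning(sprintf(
        "component (%d,%d): only %d high-confidence bins (< %d); identity covariance used",
        a, b, n, minSupport))
    }
    comps[[k]] <- CopulaComponent(a, b, thA, thB, sigma, nSupport = n)
  }
  if (sum(nSel) == 0L)
    stop("no high-confidence support; lower the confidence threshold")
  BivariateMixture(comps, gammaAb = nSel / sum(nSel))
}

#' Serialize a bivariate mixture to a parameter file
#'
#' Same key-value text format as \code{\link{writeMixtureParams}}: per
#' component (a, b) the marginal parameter pairs, the 2 x 2 covariance and
#' the support size, plus the four mixing weights.
#'
#' @param mixture a \code{\linkS4class{BivariateMixture}}.
#' @param path output (input) file path.
#' @return \code{writeBivariateParams}: \code{path} invisibly;
#'   \code{readBivariateParams}: a \code{\linkS4class{BivariateMixture}}.
#' @export
writeBivariateParams <- function(mixture, path) {
  stopifnot(is(mixture, "BivariateMixture"))
  fmt <- function(v) format(v, digits = 17)
  lines <- character(0)
  for (nm in names(mixture@components)) {
    cmp <- mixture@components[[nm]]
    pre <- paste0("comp", nm, ".")
    lines <- c(lines,
      paste0(pre, "a\t", cmp@a), paste0(pre, "b\t", cmp@b),
      paste0(pre, "rX\t", fmt(cmp@marginalX@r)),
      paste0(pre, "pX\t", fmt(cmp@marginalX@p)),
      paste0(pre, "betaX\t", fmt(cmp@marginalX@beta)),
      paste0(pre, "rY\t", fmt(cmp@marginalY@r)),
      paste0(pre, "pY\t", fmt(cmp@marginalY@p)),
      paste0(pre, "betaY\t", fmt(cmp@marginalY@beta)),
      paste0(pre, "s11\t", fmt(cmp@sigma[1, 1])),
      paste0(pre, "s12\t", fmt(cmp@sigma[1, 2])),
      paste0(pre, "s22\t", fmt(cmp@sigma[2, 2])),
      paste0(pre, "nSupport\t", cmp@nSupport),
      paste0(pre, "gamma\t", fmt(mixture@gammaAb[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeBivariateParams
#' @export
readBivariateParams <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L))
  comps <- list()
  gam <- numeric(4)
  nms <- c("00", "11", "10", "01")
  for (k in seq_along(nms)) {
    pre <- paste0("comp", nms[k], ".")
    num <- function(key) as.numeric(kv[[paste0(pre, key)]])
    sigma <- matrix(c(num("s11"), num("s12"), num("s12"), num("s22")), 2, 2)
    comps[[k]] <- CopulaComponent(
      as.integer(num("a")), as.integer(num("b")),
      ZinbParams(num("rX"), num("pX"), num("betaX")),
      ZinbParams(num("rY"), num("pY"), num("betaY")),
      sigma, nSupport = as.integer(num("nSupport")))
    gam[k] <- num("gamma")
  }
  BivariateMixture(comps, gammaAb = gam)
}
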