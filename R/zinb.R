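#' Zero-inflated negative binomial distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the zero-inflated negative binomial (ZINB) distribution with
#' dispersion \code{r}, success probability \code{p} and zero-inflation
#' weight \code{beta}:
#' \deqn{f(x) = \beta I(x=0) + (1-\beta)\frac{\Gamma(r+x)}{\Gamma(r)\,x!}
#'   p^r (1-p)^x, \quad x = 0, 1, 2, \dots}
#' The negative binomial factor is evaluated in log space
#' (\code{\link[stats]{dnbinom}}); the mean is
#' \eqn{(1-\beta)\,r(1-p)/p}.
#'
#' @param x,q vector of non-negative integer counts (for \code{pzinb},
#'   \code{q} may be negative, giving 0).
#' @param u vector of probabilities.
#' @param n number of draws.
#' @param params a \code{\linkS4class{ZinbParams}} object.
#' @param log,log.p logical; return log probabilities.
#' @return \code{dzinb} the pmf, \code{pzinb} the CDF \eqn{P(X \le q)},
#'   \code{qzinb} the smallest integer \eqn{x} with \eqn{F(x) \ge u},
#'   \code{rzinb} integer draws.
#' @examples
#' th <- ZinbParams(r = 2.5, p = 0.3, beta = 0.1)
#' dzinb(0:5, th)
#' pzinb(5, th)
#' @name zinb
NULL

#' @rdname zinb
#' @export
dzinb <- function(x, params, log = FALSE) {
  stopifnot(is(params, "ZinbParams"))
  if (any(x < 0 | x != floor(x)))
    stop("'x' must contain non-negative integers")
  nb <- stats::dnbinom(x, size = params@r, prob = params@p)
  d <- params@beta * (x == 0) + (1 - params@beta) * nb
  if (log) base::log(d) else d
}

#' @rdname zinb
#' @export
pzinb <- function(q, params, log.p = FALSE) {
  stopifnot(is(params, "ZinbParams"))
  q <- floor(q)
  cdf <- ifelse(q < 0, 0,
                params@beta +
                  (1 - params@beta) *
                    stats::pnbinom(pmax(q, 0), size = params@r,
                                   prob = params@p))
  if (log.p) base::log(cdf) else cdf
}

#' @rdname zinb
#' @export
qzinb <- function(u, params) {
  stopifnot(is(params, "ZinbParams"))
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  beta <- params@beta
  out <- numeric(length(u))
  above <- u > pzinb(0, params)
  if (any(above)) {
    # invert only the NB part: F(x) = beta + (1-beta) Fnb(x) for x >= 0
    out[above] <- stats::qnbinom((u[above] - beta) / (1 - beta),
                                 size = params@r, prob = params@p)
  }
  if (any(!is.finite(out)))
    stop("'u' too close to 1: count quantile overflows")
  as.integer(out)
}

#' @rdname zinb
#' @export
rzinb <- function(n, params) {
  stopifnot(is(params, "ZinbParams"))
  inflated <- stats::runif(n) < params@beta
  x <- stats::rnbinom(n, size = params@r, prob = params@p)
  x[inflated] <- 0L
  as.integer(x)
}

#' ZINB component mean
#'
#' Mean \eqn{(1-\beta)\,r(1-p)/p} of a zero-inflated negative binomial;
#' used for the ordering constraint between the unmodified and modified
#' mixture components.
#'
#' @param params a \code{\linkS4class{ZinbParams}} object.
#' @return the distribution mean.
#' @export
zinbMean <- function(params) {
  stopifnot(is(params, "ZinbParams"))
  (1 - params@beta) * params@r * (1 - params@p) / params@p
}
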