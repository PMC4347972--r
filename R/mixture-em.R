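## Log floor applied to emission/pmf values before taking logs, so that
## downstream HMM recursions never see -Inf.
.PMF_FLOOR <- 1e-300

.logFloor <- function(p) log(pmax(p, .PMF_FLOOR))

## Share of the zero-count mass attributable to the inflation part (rather
## than the NB part) within one component: beta / (beta + (1-beta) p^r).
.zeroInflationShare <- function(params) {
  pnb0 <- stats::dnbinom(0, size = params@r, prob = params@p)
  denom <- params@beta + (1 - params@beta) * pnb0
  if (denom <= 0) 1 else params@beta / denom
}

## Weighted NB maximum likelihood on aggregated counts: values u with
## weights v. p is profiled out as r/(r + weighted mean); r maximised
## numerically on the log scale.
.fitWeightedNb <- function(u, v, rPrev) {
  W <- sum(v)
  mbar <- sum(v * u) / W
  if (!is.finite(mbar) || mbar <= 0)
    return(NULL)  # no positive NB mass; caller keeps previous parameters
  prof <- function(logr) {
    r <- exp(logr)
    p <- r / (r + mbar)
    sum(v * (lgamma(u + r) - lgamma(r) + r * log(p) + u * log1p(-p)))
  }
  opt <- tryCatch(
    stats::optimize(prof, interval = log(c(1e-3, 1e5)), maximum = TRUE,
                    tol = 1e-9),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  r <- exp(opt$maximum)
  list(r = r, p = r / (r + mbar))
}

#' Construct a univariate ZINB mixture
#'
#' @param alpha mixing weight of the unmodified component.
#' @param theta0,theta1 \code{\linkS4class{ZinbParams}} of the unmodified
#'   (low-mean) and modified (high-mean) components.
#' @param loglikTrace optional per-iteration log-likelihood record.
#' @param sampleId sample identifier.
#' @return a \code{\linkS4class{UnivariateMixture}}.
#' @export
UnivariateMixture <- function(alpha, theta0, theta1,
                              loglikTrace = numeric(), sampleId = "sample") {
  new("UnivariateMixture", alpha = as.numeric(alpha), theta0 = theta0,
      theta1 = theta1, loglikTrace = as.numeric(loglikTrace),
      sampleId = as.character(sampleId))
}

#' Mixture density of binned counts
#'
#' Density \eqn{P(x) = \alpha f(x,\theta_0) + (1-\alpha) f(x,\theta_1)} of
#' the fitted two-component ZINB mixture.
#'
#' @param x non-negative integer counts.
#' @param mixture a \code{\linkS4class{UnivariateMixture}}.
#' @param log return log density.
#' @return density values.
#' @export
dzinbMixture <- function(x, mixture, log = FALSE) {
  d <- mixture@alpha * dzinb(x, mixture@theta0) +
    (1 - mixture@alpha) * dzinb(x, mixture@theta1)
  if (log) base::log(d) else d
}

#' Fit the two-component ZINB mixture by EM
#'
#' Fits \eqn{P(x) = \alpha f(x,\theta_0) + (1-\alpha) f(x,\theta_1)} with
#' zero-inflated negative binomial components to binned read counts.
#' Starting values follow a median split: counts at or below the median get
#' responsibility 0.9 for the first component and 0.1 for the second, and
#' vice versa above the median; the component parameters are then obtained
#' by one maximization step. Each subsequent EM iteration alternates
#' responsibilities (with the zero-count responsibility further split
#' between the inflation and the negative binomial part within each
#' component — required for a correct \eqn{\beta} update) and weighted
#' maximum-likelihood updates of \eqn{(\alpha, \beta, r, p)}, where \eqn{p}
#' is profiled out as \eqn{r/(r + \bar{x}_w)} and \eqn{r} is maximised
#' numerically. Components are relabelled if needed so that the first has
#' the smaller mean.
#'
#' @param x vector of (truncated) non-negative integer bin counts; typically
#'   from a single training chromosome.
#' @param maxIter iteration cap (default 500).
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param sampleId identifier stored on the result.
#' @return a \code{\linkS4class{UnivariateMixture}} with the per-iteration
#'   log-likelihood in \code{loglikTrace} (non-decreasing).
#' @examples
#' set.seed(1)
#' x <- c(rzinb(900, ZinbParams(1.5, 0.6, 0.3)),
#'        rzinb(100, ZinbParams(4, 0.08)))
#' fit <- fitZinbMixtureEM(x)
#' fit
#' @export
fitZinbMixtureEM <- function(x, maxIter = 500L, tol = 1e-6,
                             sampleId = "sample") {
  if (length(x) == 0L || any(x < 0) || any(x != floor(x)))
    stop("'x' must be non-negative integer counts")
  if (length(unique(x)) < 2L)
    stop("degenerate input, cannot fit two components")

  tab <- table(x)
  u <- as.integer(names(tab))
  n <- as.numeric(tab)
  N <- sum(n)
  zeroIdx <- match(0L, u)  # NA when no zeros present

  ## --- median-split initialization -------------------------------------
  med <- stats::median(x)
  low <- u <= med  # ties at the median go to the lower group
  w <- cbind(ifelse(low, 0.9, 0.1), ifelse(low, 0.1, 0.9))
  ## Zero counts are ambiguous between the inflation and the NB part, and
  ## only the total zero-inflation mass is identified by the likelihood —
  ## how it splits between the two components is a free direction. The
  ## split is resolved by attributing zero inflation to the unmodified
  ## (low-occupancy) component: its inflation share is seeded at 0.5, the
  ## modified component's at 0 (an absorbing point of the beta update, so
  ## beta1 stays 0 and all parameters become identifiable).
  zshare <- c(0.5, 0)

  alpha <- NA_real_
  theta <- list(NULL, NULL)
  mstep <- function(w, zshare, thetaPrev) {
    alphaNew <- sum(n * w[, 1]) / N
    alphaNew <- min(max(alphaNew, 1e-6), 1 - 1e-6)
    thetaNew <- vector("list", 2L)
    for (j in 1:2) {
      Wj <- sum(n * w[, j])
      v <- n * w[, j]
      zmass <- 0
      if (!is.na(zeroIdx)) {
        zmass <- n[zeroIdx] * w[zeroIdx, j] * zshare[j]
        v[zeroIdx] <- v[zeroIdx] * (1 - zshare[j])
      }
      betaj <- min(max(zmass / Wj, 0), 1 - 1e-8)
      nb <- .fitWeightedNb(u, v, NULL)
      if (is.null(nb)) {
        if (is.null(thetaPrev[[j]]))
          stop("degenerate input, cannot fit two components")
        nb <- list(r = thetaPrev[[j]]@r, p = thetaPrev[[j]]@p)
      }
      thetaNew[[j]] <- ZinbParams(nb$r, nb$p, betaj)
    }
    list(alpha = alphaNew, theta = thetaNew)
  }

  m <- mstep(w, zshare, theta)
  alpha <- m$alpha; theta <- m$theta

  ## --- EM iterations ----------------------------------------------------
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    lf <- cbind(.logFloor(dzinb(u, theta[[1]])),
                .logFloor(dzinb(u, theta[[2]])))
    la <- sweep(lf, 2, log(c(alpha, 1 - alpha)), `+`)
    mx <- pmax(la[, 1], la[, 2])
    lse <- mx + log(exp(la[, 1] - mx) + exp(la[, 2] - mx))
    ll <- sum(n * lse)
    trace <- c(trace, ll)
    if (it > 1L) {
      delta <- ll - trace[it - 1L]
      if (abs(delta) / max(abs(ll), 1) < tol) break
    }
    w <- exp(la - lse)
    zshare <- c(.zeroInflationShare(theta[[1]]),
                .zeroInflationShare(theta[[2]]))
    m <- mstep(w, zshare, theta)
    alpha <- m$alpha; theta <- m$theta
  }

  ## enforce the ordering constraint: component 0 is the low-occupancy one
  if (zinbMean(theta[[1]]) > zinbMean(theta[[2]])) {
    theta <- theta[c(2, 1)]
    alpha <- 1 - alpha
  } else if (zinbMean(theta[[1]]) == zinbMean(theta[[2]])) {
    stop("EM converged to identical components; cannot order them")
  }
  UnivariateMixture(alpha, theta[[1]], theta[[2]], loglikTrace = trace,
                    sampleId = sampleId)
}

#' Posterior probability of the modified component
#'
#' Static responsibility \eqn{P(\mathrm{component}=1 \mid x) =
#' (1-\alpha) f(x,\theta_1) / [\alpha f(x,\theta_0) +
#' (1-\alpha) f(x,\theta_1)]} under a fitted mixture (no spatial
#' information; a diagnostic complementing the HMM posterior).
#'
#' @param x non-negative integer counts.
#' @param mixture a fitted \code{\linkS4class{UnivariateMixture}}.
#' @return probabilities in [0, 1].
#' @export
posteriorComponent <- function(x, mixture) {
  stopifnot(is(mixture, "UnivariateMixture"))
  f0 <- mixture@alpha * dzinb(x, mixture@theta0)
  f1 <- (1 - mixture@alpha) * dzinb(x, mixture@theta1)
  tot <- f0 + f1
  if (any(tot == 0))
    stop("total mixture density is zero at some 'x'")
  f1 / tot
}

#' Serialize fitted mixtures to a parameter file
#'
#' Plain-text key-value format (\code{key<TAB>value} per line) holding the
#' sample id, \code{alpha}, the two component parameter triples and the
#' final log-likelihood, so a fitted model can be re-loaded to skip
#' refitting.
#'
#' @param mixture a \code{\linkS4class{UnivariateMixture}}.
#' @param path output (input) file path.
#' @return \code{writeMixtureParams}: \code{path} invisibly;
#'   \code{readMixtureParams}: a \code{\linkS4class{UnivariateMixture}}.
#' @export
writeMixtureParams <- function(mixture, path) {
  stopifnot(is(mixture, "UnivariateMixture"))
  ll <- if (length(mixture@loglikTrace))
    mixture@loglikTrace[length(mixture@loglikTrace)] else NA_real_
  kv <- c(sampleId = mixture@sampleId,
          alpha = format(mixture@alpha, digits = 17),
          r0 = format(mixture@theta0@r, digits = 17),
          p0 = format(mixture@theta0@p, digits = 17),
          beta0 = format(mixture@theta0@beta, digits = 17),
          r1 = format(mixture@theta1@r, digits = 17),
          p1 = format(mixture@theta1@p, digits = 17),
          beta1 = format(mixture@theta1@beta, digits = 17),
          loglik = format(ll, digits = 17))
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeMixtureParams
#' @export
readMixtureParams <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L))
  num <- function(k) as.numeric(kv[[k]])
  ll <- num("loglik")
  UnivariateMixture(num("alpha"),
                    ZinbParams(num("r0"), num("p0"), num("beta0")),
                    ZinbParams(num("r1"), num("p1"), num("beta1")),
                    loglikTrace = if (is.na(ll)) numeric() else ll,
                    sampleId = kv[["sampleId"]])
}
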