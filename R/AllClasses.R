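#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlevelsInUse
#' @useDynLib broadHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Zero-inflated negative binomial parameters
#'
#' Parameter triple of a zero-inflated negative binomial (ZINB) distribution:
#' a point mass of weight \code{beta} at zero mixed with a negative binomial
#' with dispersion \code{r} and success probability \code{p}, so that
#' \eqn{f(x) = \beta I(x=0) + (1-\beta)\,\Gamma(r+x)/(\Gamma(r)x!)\,p^r(1-p)^x}.
#' The mean is \eqn{(1-\beta)\,r(1-p)/p}.
#'
#' @slot r positive dispersion (size) parameter of the negative binomial part.
#' @slot p success probability in (0, 1); small \code{p} means a heavy tail.
#' @slot beta zero-inflation weight in [0, 1).
#' @export
setClass("ZinbParams",
  representation(r = "numeric", p = "numeric", beta = "numeric"))

setValidity("ZinbParams", function(object) {
  msg <- character()
  if (length(object@r) != 1L || !is.finite(object@r) || object@r <= 0)
    msg <- c(msg, "'r' must be a single finite value > 0")
  if (length(object@p) != 1L || !is.finite(object@p) ||
      object@p <= 0 || object@p >= 1)
    msg <- c(msg, "'p' must be a single value in (0, 1)")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta < 0 || object@beta >= 1)
    msg <- c(msg, "'beta' must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param r,p,beta see slot documentation.
#' @rdname ZinbParams-class
#' @export
ZinbParams <- function(r, p, beta = 0) {
  new("ZinbParams", r = as.numeric(r), p = as.numeric(p),
      beta = as.numeric(beta))
}

#' Two-component ZINB mixture
#'
#' Result of the EM fit to binned read counts: mixing weight \code{alpha} for
#' the unmodified (low-mean) component \code{theta0}, weight
#' \code{1 - alpha} for the modified (high-mean) component \code{theta1}.
#' Components are ordered so that \code{zinbMean(theta0) < zinbMean(theta1)};
#' state 0 always represents low occupancy.
#'
#' @slot alpha mixing weight of the unmodified component, in (0, 1).
#' @slot theta0,theta1 \code{\linkS4class{ZinbParams}} of the two components.
#' @slot loglikTrace per-EM-iteration log-likelihood (non-decreasing).
#' @slot sampleId sample identifier carried from the fitted track.
#' @export
setClass("UnivariateMixture",
  representation(alpha = "numeric", theta0 = "ZinbParams",
                 theta1 = "ZinbParams", loglikTrace = "numeric",
                 sampleId = "character"))

setValidity("UnivariateMixture", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must be in (0, 1)")
  if (zinbMean(object@theta0) >= zinbMean(object@theta1))
    msg <- c(msg, "mean of theta0 must be below mean of theta1")
  if (length(msg)) msg else TRUE
})

#' Per-sample binned read-count track
#'
#' Fixed-width genomic bins (a \code{GRanges} tiling each chromosome) plus one
#' non-negative integer read count per bin for a single sample. Two tracks
#' over identical bins form the input pair of the differential workflow.
#'
#' @slot bins \code{GRanges} of bins, ordered by chromosome then start; all
#'   bins except possibly the last of each chromosome share one width.
#' @slot counts integer vector, one count per bin, all \code{>= 0}.
#' @slot sampleId sample identifier.
#' @slot truncationValue the count ceiling applied by
#'   \code{\link{truncateCounts}}, or \code{NA} if no truncation was applied.
#' @export
setClass("BinnedTrack",
  representation(bins = "GRanges", counts = "integer", sampleId = "character",
                 truncationValue = "numeric"))

setValidity("BinnedTrack", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@bins))
    msg <- c(msg, "length(counts) must equal number of bins")
  if (length(object@counts) && min(object@counts) < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (!is.na(object@truncationValue) && length(object@counts) &&
      max(object@counts) > object@truncationValue)
    msg <- c(msg, "counts exceed the recorded truncation value")
  if (length(msg)) msg else TRUE
})

#' Hidden Markov model with fixed emission densities
#'
#' A K-state HMM whose emission distributions are fixed (supplied as per-state
#' log-density functions and never re-estimated); Baum-Welch updates only the
#' transition matrix and initial distribution. K = 2 for single-sample
#' segmentation, K = 4 for differential analysis. Transitions between all
#' states, including self transitions, are allowed.
#'
#' @slot nStates number of hidden states K.
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initial length-K initial state distribution.
#' @slot logEmission list of K functions; each maps the per-chromosome
#'   observation object (a count vector, or a two-column count matrix in the
#'   bivariate case) to a vector of per-bin log emission densities.
#' @slot stateNames character labels for the states.
#' @export
setClass("HmmModel",
  representation(nStates = "integer", transition = "matrix",
                 initial = "numeric", logEmission = "list",
                 stateNames = "character"))

setValidity("HmmModel", function(object) {
  K <- object@nStates
  msg <- character()
  if (!identical(dim(object@transition), c(K, K)))
    msg <- c(msg, "'transition' must be K x K")
  else {
    if (any(object@transition < 0))
      msg <- c(msg, "'transition' entries must be >= 0")
    if (any(abs(rowSums(object@transition) - 1) > 1e-12))
      msg <- c(msg, "'transition' rows must sum to 1 (tol 1e-12)")
  }
  if (length(object@initial) != K || any(object@initial < 0) ||
      abs(sum(object@initial) - 1) > 1e-12)
    msg <- c(msg, "'initial' must be a length-K probability vector")
  if (length(object@logEmission) != K)
    msg <- c(msg, "'logEmission' must hold one function per state")
  if (length(object@stateNames) != K)
    msg <- c(msg, "'stateNames' must have one label per state")
  if (length(msg)) msg else TRUE
})

#' Per-bin posterior state probabilities
#'
#' Forward-backward output: for every genomic bin the posterior probability of
#' each hidden state (rows sum to 1), plus the total data log-likelihood
#' summed over chromosomes.
#'
#' @slot bins \code{GRanges} of the underlying bins.
#' @slot gamma bins x K matrix of posterior state probabilities.
#' @slot loglik total log-likelihood of the observations under the model.
#' @slot stateNames column labels of \code{gamma}.
#' @export
setClass("PosteriorTrack",
  representation(bins = "GRanges", gamma = "matrix", loglik = "numeric",
                 stateNames = "character"))

setValidity("PosteriorTrack", function(object) {
  msg <- character()
  if (nrow(object@gamma) != length(object@bins))
    msg <- c(msg, "nrow(gamma) must equal number of bins")
  if (length(object@stateNames) != ncol(object@gamma))
    msg <- c(msg, "'stateNames' must match ncol(gamma)")
  if (nrow(object@gamma)) {
    if (any(object@gamma < -1e-12) || any(object@gamma > 1 + 1e-12))
      msg <- c(msg, "gamma entries must lie in [0, 1]")
    if (max(abs(rowSums(object@gamma) - 1)) > 1e-9)
      msg <- c(msg, "gamma rows must sum to 1 (tol 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' One Gaussian-copula emission component
#'
#' Bivariate count distribution for one combination (a, b) of per-sample
#' modification states: ZINB marginals \code{marginalX} (sample A, state a)
#' and \code{marginalY} (sample B, state b) coupled by a Gaussian copula with
#' covariance \code{sigma} estimated on probability-integral-transformed
#' counts. \code{sigma} is stored as estimated; it is rescaled to a
#' correlation matrix when rectangle probabilities are evaluated, since the
#' transformed margins are standard normal by construction.
#'
#' @slot a,b 0/1 indicators: is sample A (resp. B) modified in this component.
#' @slot marginalX,marginalY \code{\linkS4class{ZinbParams}} marginals.
#' @slot sigma symmetric positive-definite 2 x 2 covariance of the
#'   transformed pair; its off-diagonal carries the copula correlation.
#' @slot nSupport number of high-confidence bins used for the estimate.
#' @export
setClass("CopulaComponent",
  representation(a = "integer", b = "integer", marginalX = "ZinbParams",
                 marginalY = "ZinbParams", sigma = "matrix",
                 nSupport = "integer"))

setValidity("CopulaComponent", function(object) {
  msg <- character()
  if (!object@a %in% c(0L, 1L) || !object@b %in% c(0L, 1L))
    msg <- c(msg, "'a' and 'b' must be 0 or 1")
  s <- object@sigma
  if (!identical(dim(s), c(2L, 2L)) || abs(s[1, 2] - s[2, 1]) > 1e-12)
    msg <- c(msg, "'sigma' must be a symmetric 2 x 2 matrix")
  else {
    if (s[1, 1] <= 0 || s[2, 2] <= 0 || det(s) <= 0)
      msg <- c(msg, "'sigma' must be positive definite")
    else if (abs(s[1, 2] / sqrt(s[1, 1] * s[2, 2])) >= 1)
      msg <- c(msg, "copula correlation must satisfy |rho| < 1")
  }
  if (length(msg)) msg else TRUE
})

#' Four-component bivariate copula mixture
#'
#' The four \code{\linkS4class{CopulaComponent}}s indexed by
#' (a, b) in \{0,1\}^2, with mixing weights \code{gammaAb} (the fraction of
#' high-confidence bins supporting each component). The weights are a
#' diagnostic; in the 4-state HMM the transition structure supersedes them.
#'
#' @slot components list of four components, named
#'   \code{"00"}, \code{"11"}, \code{"10"}, \code{"01"} (state order of the
#'   differential HMM: both-unmodified, both-modified, A-only, B-only).
#' @slot gammaAb four mixing weights summing to 1, same names.
#' @export
setClass("BivariateMixture",
  representation(components = "list", gammaAb = "numeric"))

setValidity("BivariateMixture", function(object) {
  msg <- character()
  want <- c("00", "11", "10", "01")
  if (!identical(names(object@components), want))
    msg <- c(msg, "components must be named '00','11','10','01' in order")
  if (!all(vapply(object@components, is, TRUE, class2 = "CopulaComponent")))
    msg <- c(msg, "all components must be CopulaComponent objects")
  if (length(object@gammaAb) != 4L || any(object@gammaAb < 0) ||
      abs(sum(object@gammaAb) - 1) > 1e-9)
    msg <- c(msg, "'gammaAb' must be four non-negative weights summing to 1")
  if (length(msg)) msg else TRUE
})

#' Region-calling configuration
#'
#' Tuning parameters of the single-sample and differential workflows, all
#' with the defaults used throughout: 1000 bp bins, posterior threshold
#' \code{lambda} = 0.5 (equivalent to the maximal-probability state in the
#' two-state model), covariance-subset confidence 0.9, count truncation at
#' the 0.999 genome-wide quantile.
#'
#' @slot binSize bin width in basepairs.
#' @slot lambda posterior threshold for calling a bin modified, in [0, 1).
#' @slot confidence posterior cutoff selecting high-confidence bins for
#'   copula covariance estimation; must exceed \code{lambda}.
#' @slot trainChrom chromosome used for the mixture fit; \code{NA} means the
#'   largest chromosome present.
#' @slot truncationQuantile genome-wide count quantile for truncation.
#' @slot emMaxIter,emTol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @slot bwMaxIter,bwTol Baum-Welch iteration cap and tolerance.
#' @slot minSupport minimum high-confidence bins per copula component before
#'   falling back to the identity covariance.
#' @slot seed integer seed recorded with the run (the calling workflows are
#'   deterministic; the seed matters for simulation).
#' @export
setClass("CallingConfig",
  representation(binSize = "integer", lambda = "numeric",
                 confidence = "numeric", trainChrom = "character",
                 truncationQuantile = "numeric", emMaxIter = "integer",
                 emTol = "numeric", bwMaxIter = "integer", bwTol = "numeric",
                 minSupport = "integer", seed = "integer"))

setValidity("CallingConfig", function(object) {
  msg <- character()
  if (object@binSize <= 0L) msg <- c(msg, "'binSize' must be > 0")
  if (object@lambda < 0 || object@lambda >= 1)
    msg <- c(msg, "'lambda' must be in [0, 1)")
  if (object@confidence <= object@lambda || object@confidence >= 1)
    msg <- c(msg, "'confidence' must be in (lambda, 1)")
  if (object@truncationQuantile <= 0 || object@truncationQuantile > 1)
    msg <- c(msg, "'truncationQuantile' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation specification
#'
#' Ground-truth container for the seeded simulators: chromosome layout, the
#' true hidden-state transition matrix, the true per-sample ZINB mixtures and
#' (bivariate case) the per-component copula correlations.
#'
#' @slot nChromosomes number of simulated chromosomes.
#' @slot binsPerChromosome bins on each chromosome.
#' @slot binSize bin width in basepairs.
#' @slot transition true K x K transition matrix (K = 2 univariate,
#'   K = 4 bivariate, state order as in the corresponding HMM).
#' @slot mixtureA,mixtureB true \code{\linkS4class{UnivariateMixture}} of
#'   each sample (\code{mixtureB} ignored in the univariate case).
#' @slot rho named per-component copula correlations
#'   (\code{"00"}, \code{"11"}, \code{"10"}, \code{"01"}).
#' @slot seed integer seed.
#' @export
setClass("SimulationSpec",
  representation(nChromosomes = "integer", binsPerChromosome = "integer",
                 binSize = "integer", transition = "matrix",
                 mixtureA = "UnivariateMixture", mixtureB = "UnivariateMixture",
                 rho = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L || object@binsPerChromosome < 1L)
    msg <- c(msg, "need at least one chromosome and one bin")
  K <- nrow(object@transition)
  if (!K %in% c(2L, 4L) || ncol(object@transition) != K ||
      any(object@transition < 0) ||
      any(abs(rowSums(object@transition) - 1) > 1e-9))
    msg <- c(msg, "'transition' must be a 2x2 or 4x4 stochastic matrix")
  if (K == 4L) {
    if (!identical(names(object@rho), c("00", "11", "10", "01")))
      msg <- c(msg, "'rho' must be named '00','11','10','01'")
    if (any(abs(object@rho) >= 1))
      msg <- c(msg, "all |rho| must be < 1")
  }
  if (length(msg)) msg else TRUE
})
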