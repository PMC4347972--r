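#' Simulation specification
#'
#' Ground-truth settings for the seeded track simulators. The defaults are
#' the package's demo conditions: 2 chromosomes of 5000 bins at 1000 bp,
#' hidden-state self-transitions of 0.95 (broad-domain persistence),
#' component means of about 3 (unmodified) and 25 (modified) counts per
#' bin, copula correlation 0.5 in the two concordant states and 0 in the
#' discordant ones.
#'
#' @param nChromosomes number of chromosomes.
#' @param binsPerChromosome bins per chromosome.
#' @param binSize bin width in basepairs.
#' @param nStates 2 (univariate) or 4 (bivariate); sets the default
#'   transition matrix size.
#' @param selfTransition diagonal of the default transition matrix.
#' @param transition explicit transition matrix (overrides
#'   \code{selfTransition}).
#' @param mixtureA,mixtureB true per-sample mixtures; defaults use
#'   \eqn{\theta_0 = (r=2, p=0.4, \beta=0.1)} (mean 2.7) and
#'   \eqn{\theta_1 = (r=5, p=1/6, \beta=0)} (mean 25).
#' @param rho named per-component copula correlations
#'   (\code{"00"}, \code{"11"}, \code{"10"}, \code{"01"}).
#' @param seed integer seed.
#' @return a \code{\linkS4class{SimulationSpec}}.
#' @export
simulationSpec <- function(nChromosomes = 2L, binsPerChromosome = 5000L,
                           binSize = 1000L, nStates = 4L,
                           selfTransition = 0.95, transition = NULL,
                           mixtureA = NULL, mixtureB = NULL,
                           rho = c("00" = 0.5, "11" = 0.5,
                                   "10" = 0, "01" = 0),
                           seed = 1L) {
  if (is.null(transition))
    transition <- .defaultTransition(as.integer(nStates),
                                     self = selfTransition)
  defaultMixture <- function(id)
    UnivariateMixture(0.5, ZinbParams(2, 0.4, 0.1),
                      ZinbParams(5, 1 / 6, 0), sampleId = id)
  if (is.null(mixtureA)) mixtureA <- defaultMixture("simA")
  if (is.null(mixtureB)) mixtureB <- defaultMixture("simB")
  new("SimulationSpec", nChromosomes = as.integer(nChromosomes),
      binsPerChromosome = as.integer(binsPerChromosome),
      binSize = as.integer(binSize), transition = transition,
      mixtureA = mixtureA, mixtureB = mixtureB, rho = rho,
      seed = as.integer(seed))
}

.simBins <- function(spec) {
  sl <- stats::setNames(
    rep(as.numeric(spec@binsPerChromosome) * spec@binSize,
        spec@nChromosomes),
    paste0("chr", seq_len(spec@nChromosomes)))
  genomeBins(sl, spec@binSize)
}

## One Markov-chain state path per chromosome, uniform initial state.
.simStatePath <- function(nBins, A) {
  K <- nrow(A)
  s <- integer(nBins)
  s[1] <- sample.int(K, 1L)
  if (nBins > 1L)
    for (t in 2:nBins)
      s[t] <- sample.int(K, 1L, prob = A[s[t - 1L], ])
  s
}

#' Simulate a univariate binned track with known truth
#'
#' Hidden states are drawn from the Markov chain of the spec (one path per
#' chromosome); each bin's count is then drawn from the ZINB component of
#' its state. Reproducible given the spec's seed.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}} with a 2 x 2
#'   transition matrix.
#' @return a list with \code{track} (a \code{\linkS4class{BinnedTrack}})
#'   and \code{states} (integer truth per bin: 1 = unmodified,
#'   2 = modified).
#' @export
simulateUnivariate <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  if (nrow(spec@transition) != 2L)
    stop("univariate simulation needs a 2 x 2 transition matrix")
  set.seed(spec@seed)
  b <- .simBins(spec)
  states <- unlist(lapply(seq_len(spec@nChromosomes), function(i)
    .simStatePath(spec@binsPerChromosome, spec@transition)))
  x <- integer(length(states))
  for (s in 1:2) {
    i <- states == s
    x[i] <- rzinb(sum(i), component(spec@mixtureA, s - 1L))
  }
  list(track = BinnedTrack(b, x, sampleId = spec@mixtureA@sampleId),
       states = states)
}

#' Simulate a bivariate track pair with known truth
#'
#' Hidden (a, b) states are drawn from the 4-state Markov chain (state
#' order both-unmodified, both-modified, A-only, B-only); per bin a
#' bivariate normal pair with the state's copula correlation is drawn and
#' each coordinate is mapped through the standard-normal CDF and the ZINB
#' count quantile function of the corresponding marginal. This copula
#' construction guarantees that each sample's counts within a state follow
#' the marginal ZINB exactly. Reproducible given the spec's seed.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}} with a 4 x 4
#'   transition matrix.
#' @return a list with \code{trackA}, \code{trackB}
#'   (\code{\linkS4class{BinnedTrack}}s) and \code{states} (integer truth
#'   per bin, 1-4 in the state order above).
#' @export
simulateBivariate <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  if (nrow(spec@transition) != 4L)
    stop("bivariate simulation needs a 4 x 4 transition matrix")
  if (any(abs(spec@rho) >= 1)) stop("all |rho| must be < 1")
  set.seed(spec@seed)
  b <- .simBins(spec)
  states <- unlist(lapply(seq_len(spec@nChromosomes), function(i)
    .simStatePath(spec@binsPerChromosome, spec@transition)))
  n <- length(states)
  ab <- list(c(0L, 0L), c(1L, 1L), c(1L, 0L), c(0L, 1L))
  x <- integer(n); y <- integer(n)
  for (s in 1:4) {
    i <- which(states == s)
    if (!length(i)) next
    rho <- spec@rho[[s]]
    zx <- stats::rnorm(length(i))
    zy <- rho * zx + sqrt(1 - rho^2) * stats::rnorm(length(i))
    x[i] <- qzinb(stats::pnorm(zx), component(spec@mixtureA, ab[[s]][1]))
    y[i] <- qzinb(stats::pnorm(zy), component(spec@mixtureB, ab[[s]][2]))
  }
  list(trackA = BinnedTrack(b, x, sampleId = spec@mixtureA@sampleId),
       trackB = BinnedTrack(b, y, sampleId = spec@mixtureB@sampleId),
       states = states)
}
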