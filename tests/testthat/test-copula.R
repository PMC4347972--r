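test_that("probability integral transform hits its anchor points", {
  # marginal built so that F(0) = 0.375 + 0.625 * 0.2 = 0.5 exactly
  th <- ZinbParams(1, 0.2, 0.375)
  expect_equal(pitTransform(0, th), 0, tolerance = 1e-12)
  # below-support counts clip to a large negative but finite score
  z <- pitTransform(-1, ZinbParams(2, 0.5, 0))
  expect_true(is.finite(z))
  expect_lt(z, -6)
  # round trip: the count quantile of Phi(z) recovers the count
  th2 <- ZinbParams(2.5, 0.3, 0.1)
  x <- c(0:15, 30L)
  expect_identical(qzinb(pnorm(pitTransform(x, th2)), th2), x)
})

test_that("independent copula components factorize into their marginals", {
  mx <- ZinbParams(2, 0.4, 0.1)
  my <- ZinbParams(5, 1 / 6, 0)
  cmp <- CopulaComponent(0L, 1L, mx, my, sigma = diag(2))
  grid <- expand.grid(x = 0:25, y = 0:60)
  lp <- bivariateLogPmf(grid$x, grid$y, cmp)
  ref <- log(dzinb(grid$x, mx)) + log(dzinb(grid$y, my))
  expect_lt(max(abs(lp - ref)), 1e-8)
})

test_that("copula pmf matches a dense midpoint quadrature oracle", {
  mx <- ZinbParams(2.5, 0.3, 0.1)
  my <- ZinbParams(4, 0.2, 0)
  rho <- 0.6
  cmp <- CopulaComponent(1L, 1L, mx, my,
                         sigma = matrix(c(1, rho, rho, 1), 2))
  for (xy in list(c(3, 5), c(0, 2), c(7, 1))) {
    x <- xy[1]; y <- xy[2]
    lx <- if (x == 0) -8.5 else qnorm(pzinb(x - 1, mx))
    hx <- qnorm(pzinb(x, mx))
    ly <- if (y == 0) -8.5 else qnorm(pzinb(y - 1, my))
    hy <- qnorm(pzinb(y, my))
    q <- midpointRectProb(lx, hx, ly, hy, rho, n = 400)
    expect_lt(abs(exp(bivariateLogPmf(x, y, cmp)) - q), 1e-6)
  }
})

test_that("copula pmf normalizes and preserves its marginals", {
  mx <- ZinbParams(2, 0.4, 0.1)
  my <- ZinbParams(3, 0.3, 0)
  rho <- 0.5
  cmp <- CopulaComponent(1L, 1L, mx, my,
                         sigma = matrix(c(1, rho, rho, 1), 2))
  xs <- 0:40; ys <- 0:60
  grid <- expand.grid(x = xs, y = ys)
  p <- matrix(exp(bivariateLogPmf(grid$x, grid$y, cmp)), nrow = length(xs))
  expect_gt(sum(p), 0.9999)
  # marginalization over y recovers the ZINB pmf of x (copulas preserve
  # marginals)
  tailMass <- 1 - pzinb(max(ys), my)
  expect_lt(max(abs(rowSums(p) - dzinb(xs, mx))), 1e-5 + tailMass)
})

test_that("copula pmf is symmetric under a joint sample swap", {
  mx <- ZinbParams(2, 0.4, 0.1)
  my <- ZinbParams(4, 0.15, 0)
  rho <- -0.4
  fwd <- CopulaComponent(1L, 0L, mx, my, matrix(c(1, rho, rho, 1), 2))
  rev <- CopulaComponent(0L, 1L, my, mx, matrix(c(1, rho, rho, 1), 2))
  grid <- expand.grid(x = 0:12, y = 0:12)
  expect_identical(bivariateLogPmf(grid$x, grid$y, fwd),
                   bivariateLogPmf(grid$y, grid$x, rev))
})

test_that("dependence increases concordant-tail mass monotonically", {
  mx <- ZinbParams(2, 0.4, 0)
  my <- ZinbParams(2, 0.4, 0)
  medx <- qzinb(0.5, mx)
  pts <- expand.grid(x = medx + c(2, 4), y = medx + c(2, 4))
  prev <- rep(-Inf, nrow(pts))
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    cmp <- CopulaComponent(1L, 1L, mx, my, matrix(c(1, rho, rho, 1), 2))
    cur <- bivariateLogPmf(pts$x, pts$y, cmp)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("component covariances are recovered from high-confidence calls", {
  rho <- c("00" = 0.0, "11" = 0.7, "10" = 0.4, "01" = 0.4)
  spec <- simulationSpec(nChromosomes = 2, binsPerChromosome = 5000,
                         rho = rho, seed = 17)
  sim <- simulateBivariate(spec)
  uniModel <- function(mix) HmmModel(
    matrix(c(.95, .05, .05, .95), 2), list(
      function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
      function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300))),
    stateNames = c("unmodified", "modified"))
  postA <- forwardBackward(sim$trackA, uniModel(spec@mixtureA))
  postB <- forwardBackward(sim$trackB, uniModel(spec@mixtureB))
  biv <- estimateComponentCovariance(sim$trackA, sim$trackB, postA, postB,
                                     spec@mixtureA, spec@mixtureB)
  for (nm in names(rho)) {
    expect_lt(abs(copulaCorrelation(component(biv, nm)) - rho[[nm]]), 0.05)
    expect_gt(component(biv, nm)@nSupport, 100)
  }
  expect_equal(sum(mixingWeights(biv)), 1, tolerance = 1e-12)
})

test_that("self-pairing yields near-maximal correlation, independence near zero", {
  spec <- simulationSpec(nChromosomes = 1, binsPerChromosome = 20000,
                         nStates = 2, seed = 23)
  simA <- simulateUnivariate(spec)
  mix <- spec@mixtureA
  uniModel <- HmmModel(spec@transition, list(
    function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
    function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300))),
    stateNames = c("unmodified", "modified"))
  postA <- forwardBackward(simA$track, uniModel)

  # a track against itself: transformed pairs are identical, so the
  # concordant components sit at the correlation cap
  suppressWarnings(
    bivSelf <- estimateComponentCovariance(simA$track, simA$track, postA,
                                           postA, mix, mix))
  expect_gt(copulaCorrelation(component(bivSelf, "00")), 0.95)
  expect_gt(copulaCorrelation(component(bivSelf, "11")), 0.95)

  # an independently simulated second track: all correlations near zero
  spec2 <- spec; spec2@seed <- 29L
  simB <- simulateUnivariate(spec2)
  postB <- forwardBackward(simB$track, uniModel)
  suppressWarnings(
    bivInd <- estimateComponentCovariance(simA$track, simB$track, postA,
                                          postB, mix, mix))
  for (nm in c("00", "11", "10", "01")) {
    cmp <- component(bivInd, nm)
    if (cmp@nSupport >= 50)
      expect_lt(abs(copulaCorrelation(cmp)), 0.05)
  }
})

test_that("sparse components fall back to the identity covariance", {
  spec <- simulationSpec(nChromosomes = 1, binsPerChromosome = 2000,
                         nStates = 2, seed = 3)
  sim <- simulateUnivariate(spec)
  mix <- spec@mixtureA
  uniModel <- HmmModel(spec@transition, list(
    function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
    function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300))),
    stateNames = c("unmodified", "modified"))
  post <- forwardBackward(sim$track, uniModel)
  # the discordant components of a self-comparison have (almost) no support
  warns <- capture_warnings(
    biv <- estimateComponentCovariance(sim$track, sim$track, post, post,
                                       mix, mix))
  expect_true(all(grepl("identity covariance", warns)))
  expect_gte(length(warns), 1L)
  expect_identical(component(biv, "10")@sigma, diag(2))
})

test_that("bivariate parameter files round-trip", {
  comps <- list(
    CopulaComponent(0L, 0L, ZinbParams(2, .4, .1), ZinbParams(2, .4, .1),
                    matrix(c(1.1, .3, .3, .9), 2), 120L),
    CopulaComponent(1L, 1L, ZinbParams(5, 1/6, 0), ZinbParams(5, .2, 0),
                    matrix(c(1, .65, .65, 1), 2), 300L),
    CopulaComponent(1L, 0L, ZinbParams(5, 1/6, 0), ZinbParams(2, .4, .1),
                    diag(2), 10L),
    CopulaComponent(0L, 1L, ZinbParams(2, .4, .1), ZinbParams(5, .2, 0),
                    diag(2), 15L))
  biv <- BivariateMixture(comps, c(0.3, 0.5, 0.1, 0.1))
  path <- withr::local_tempfile(fileext = ".txt")
  writeBivariateParams(biv, path)
  back <- readBivariateParams(path)
  expect_equal(component(back, "11")@sigma,
               component(biv, "11")@sigma, tolerance = 1e-14)
  expect_equal(mixingWeights(back), mixingWeights(biv), tolerance = 1e-14)
  expect_identical(component(back, "10")@nSupport, 10L)
  expect_equal(component(back, "01")@marginalY@p, 0.2, tolerance = 1e-15)
})
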