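test_that("single-position posterior is the normalized initial-times-emission", {
  logE <- matrix(log(c(0.2, 0.6)), 1, 2)
  model <- matrixHmm(logE, matrix(c(.7, .3, .4, .6), 2, byrow = TRUE),
                     c(0.5, 0.5))
  post <- forwardBackward(list(1L), model)
  expected <- c(0.5 * 0.2, 0.5 * 0.6)
  expect_equal(posteriorMatrix(post)[1, ], expected / sum(expected),
               tolerance = 1e-14)
  expect_equal(trackLogLik(post), log(sum(expected)), tolerance = 1e-14)
})

test_that("symmetric models give uniform posteriors", {
  Tn <- 10; K <- 3
  logE <- matrix(log(0.3), Tn, K)  # identical emissions in every state
  A <- matrix(1 / K, K, K)         # doubly stochastic
  model <- matrixHmm(logE, A, rep(1 / K, K))
  post <- forwardBackward(list(seq_len(Tn)), model)
  expect_equal(posteriorMatrix(post),
               matrix(1 / K, Tn, K), tolerance = 1e-12)
})

test_that("forward-backward matches exhaustive path enumeration", {
  for (K in 2:4) {
    set.seed(100 + K)
    inst <- randomHmmInstance(K, 6)
    model <- matrixHmm(inst$logE, inst$A, inst$init)
    post <- forwardBackward(list(1:6), model)
    oracle <- enumPosterior(inst$logE, inst$A, inst$init)
    expect_equal(posteriorMatrix(post), oracle$gamma, tolerance = 1e-12)
    expect_equal(trackLogLik(post), oracle$loglik, tolerance = 1e-12)
  }
})

test_that("recursions restart at chromosome boundaries and pool the loglik", {
  set.seed(42)
  inst <- randomHmmInstance(3, 12)
  model <- matrixHmm(inst$logE, inst$A, inst$init)
  # two chromosomes indexing disjoint parts of the emission matrix
  post <- forwardBackward(list(chrA = 1:5, chrB = 6:12), model)
  oA <- enumPosterior(inst$logE[1:5, ], inst$A, inst$init)
  oB <- enumPosterior(inst$logE[6:12, ], inst$A, inst$init)
  expect_equal(trackLogLik(post), oA$loglik + oB$loglik, tolerance = 1e-10)
  expect_equal(posteriorMatrix(post), rbind(oA$gamma, oB$gamma),
               tolerance = 1e-10)
  # permuting chromosome order permutes posteriors and keeps the loglik
  post2 <- forwardBackward(list(chrB = 6:12, chrA = 1:5), model)
  expect_equal(trackLogLik(post2), trackLogLik(post), tolerance = 1e-12)
  expect_equal(posteriorMatrix(post2), rbind(oB$gamma, oA$gamma),
               tolerance = 1e-10)
})

test_that("an observation impossible in every state is reported by position", {
  logE <- matrix(c(0, 0, -Inf, -Inf, 0, 0), 3, 2, byrow = TRUE)
  model <- matrixHmm(logE, matrix(0.5, 2, 2), c(0.5, 0.5))
  expect_error(forwardBackward(list(1:3), model), "position 2")
})

test_that("Baum-Welch recovers the transition frequencies of a forced path", {
  set.seed(31)
  path <- integer(400)
  path[1] <- 1L
  trueA <- matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)
  for (t in 2:400) path[t] <- sample(1:2, 1, prob = trueA[path[t - 1], ])
  # emissions so separated that the state path is fully determined
  model <- HmmModel(matrix(c(.5, .5, .5, .5), 2), list(
    function(o) ifelse(o == 1L, 0, -1000),
    function(o) ifelse(o == 2L, 0, -1000)))
  fit <- baumWelch(list(path), model, maxIter = 50, tol = 1e-12)
  # count-ratio oracle: empirical transition frequencies of the path
  emp <- prop.table(table(factor(path[-400], 1:2),
                          factor(path[-1], 1:2)), margin = 1)
  expect_equal(transitionMatrix(fit), unclass(as.matrix(emp)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("Baum-Welch loglik is non-decreasing from random starts", {
  set.seed(77)
  spec <- simulationSpec(nChromosomes = 1, binsPerChromosome = 300,
                         nStates = 2, seed = 8)
  sim <- simulateUnivariate(spec)
  mix <- spec@mixtureA
  emis <- list(function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
               function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300)))
  for (i in 1:20) {
    A0 <- randomStochastic(2)
    p0 <- runif(2); p0 <- p0 / sum(p0)
    fit <- baumWelch(sim$track, HmmModel(A0, emis, initial = p0),
                     maxIter = 15, tol = 1e-12)
    tr <- attr(fit, "loglikTrace")
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
  }
})

test_that("decoding rules honour thresholds and tie-breaks", {
  b <- genomeBins(c(chrA = 3000), 1000)
  post <- new("PosteriorTrack", bins = b,
              gamma = matrix(c(0.3, 0.7, 0.5, 0.5, 0.9, 0.1), 3, 2,
                             byrow = TRUE),
              loglik = -1, stateNames = c("unmodified", "modified"))
  expect_identical(as.integer(decodeStates(post, "threshold", lambda = 0.5,
                                           state = 2L)),
                   c(2L, 1L, 1L))
  # argmax ties break toward the lower state index
  expect_identical(as.integer(decodeStates(post, "max")), c(2L, 1L, 1L))
  expect_error(decodeStates(post, "threshold", lambda = 1), "lambda")
  expect_error(decodeStates(post, "threshold", lambda = -0.1), "lambda")
})

test_that("posterior decoding recovers planted states on separated data", {
  spec <- simulationSpec(nChromosomes = 1, binsPerChromosome = 5000,
                         nStates = 2, seed = 13)
  sim <- simulateUnivariate(spec)
  mix <- spec@mixtureA
  model <- HmmModel(spec@transition, list(
    function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
    function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300))))
  post <- forwardBackward(sim$track, model)
  labels <- decodeStates(post, "max")
  expect_gte(mean(labels == sim$states), 0.99)
  # posterior rows are proper distributions
  expect_equal(rowSums(posteriorMatrix(post)), rep(1, 5000),
               tolerance = 1e-9)
})

test_that("posterior tracks export one bedGraph per state", {
  spec <- simulationSpec(nChromosomes = 2, binsPerChromosome = 20,
                         nStates = 2, seed = 2)
  sim <- simulateUnivariate(spec)
  mix <- spec@mixtureA
  model <- HmmModel(spec@transition, list(
    function(o) log(pmax(dzinb(o, component(mix, 0L)), 1e-300)),
    function(o) log(pmax(dzinb(o, component(mix, 1L)), 1e-300))),
    stateNames = c("unmodified", "modified"))
  post <- forwardBackward(sim$track, model)
  dir <- withr::local_tempdir()
  paths <- exportPosteriorBedGraph(post, file.path(dir, "demo"))
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
  reimported <- rtracklayer::import(paths[2], format = "bedGraph")
  expect_equal(sum(score(reimported) * width(reimported) / 1000),
               sum(posteriorMatrix(post)[, 2]), tolerance = 1e-4)
})
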