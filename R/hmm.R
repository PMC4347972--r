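#' Construct a hidden Markov model with fixed emissions
#'
#' @param transition K x K row-stochastic matrix.
#' @param logEmission list of K per-state log-density functions (each maps
#'   the per-chromosome observation object to a vector of log densities).
#' @param initial length-K initial distribution; uniform by default.
#' @param stateNames state labels; \code{state1..stateK} by default.
#' @return an \code{\linkS4class{HmmModel}}.
#' @export
HmmModel <- function(transition, logEmission, initial = NULL,
                     stateNames = NULL) {
  K <- length(logEmission)
  if (is.null(initial)) initial <- rep(1 / K, K)
  if (is.null(stateNames)) stateNames <- paste0("state", seq_len(K))
  new("HmmModel", nStates = as.integer(K), transition = transition,
      initial = as.numeric(initial), logEmission = logEmission,
      stateNames = as.character(stateNames))
}

## Default transition start: strong self-transition reflecting the spatial
## persistence of broad domains; uniform off-diagonal.
.defaultTransition <- function(K, self = 0.9) {
  A <- matrix((1 - self) / (K - 1), K, K)
  diag(A) <- self
  A
}

## Normalize 'obs' into a named list of per-chromosome observation objects.
## Accepts a list (returned as is), a BinnedTrack (counts split by
## chromosome), a bare vector or a two-column matrix (single sequence).
.asObsList <- function(obs) {
  if (is(obs, "BinnedTrack")) {
    chrom <- as.character(seqnames(bins(obs)))
    return(split(counts(obs), factor(chrom, levels = unique(chrom))))
  }
  if (is.list(obs)) return(obs)
  list(obs)
}

## Per-chromosome log-emission matrix, evaluated once per unique observation
## (counts are small integers repeated genome-wide).
.emissionMatrix <- function(o, model) {
  K <- model@nStates
  if (is.matrix(o)) {
    key <- paste(o[, 1], o[, 2])
    first <- !duplicated(key)
    uo <- o[first, , drop = FALSE]
    idx <- match(key, key[first])
  } else {
    uo <- unique(o)
    idx <- match(o, uo)
  }
  E <- vapply(model@logEmission, function(f) as.numeric(f(uo)),
              numeric(if (is.matrix(uo)) nrow(uo) else length(uo)))
  E <- matrix(E, ncol = K)
  E[idx, , drop = FALSE]
}

## Placeholder single-basepair bins when posteriors are computed for bare
## sequences (tests, oracles) rather than genomic tracks.
.placeholderBins <- function(obsList) {
  lens <- vapply(obsList, function(o) if (is.matrix(o)) nrow(o) else length(o),
                 integer(1))
  nms <- names(obsList)
  if (is.null(nms)) nms <- paste0("seq", seq_along(obsList))
  GRanges(rep(nms, lens),
          IRanges(start = unlist(lapply(lens, seq_len)), width = 1L))
}

#' Forward-backward posterior state probabilities
#'
#' Computes per-bin posterior probabilities of every hidden state with the
#' scaled forward-backward algorithm. The recursion restarts from the
#' initial distribution at every chromosome boundary; the log-likelihood is
#' summed over chromosomes.
#'
#' @param obs observations: a \code{\linkS4class{BinnedTrack}}, a list of
#'   per-chromosome count vectors (or two-column count matrices in the
#'   bivariate case), or a single vector/matrix.
#' @param model an \code{\linkS4class{HmmModel}} with fixed emissions.
#' @param bins optional \code{GRanges} of the underlying bins (taken from
#'   \code{obs} when it is a track; placeholder coordinates otherwise).
#' @return a \code{\linkS4class{PosteriorTrack}}.
#' @export
forwardBackward <- function(obs, model, bins = NULL) {
  stopifnot(is(model, "HmmModel"))
  obsList <- .asObsList(obs)
  if (is.null(bins))
    bins <- if (is(obs, "BinnedTrack")) bins(obs) else
      .placeholderBins(obsList)
  pieces <- lapply(obsList, function(o)
    .fbScaled(.emissionMatrix(o, model), model@transition, model@initial))
  gamma <- do.call(rbind, lapply(pieces, `[[`, "gamma"))
  loglik <- sum(vapply(pieces, `[[`, numeric(1), "loglik"))
  new("PosteriorTrack", bins = bins, gamma = gamma, loglik = loglik,
      stateNames = model@stateNames)
}

#' Estimate transition probabilities by Baum-Welch
#'
#' EM re-estimation of the transition matrix and initial distribution with
#' the emission densities held fixed (they come from the mixture fit and are
#' never updated). Expected transition counts are pooled across chromosomes
#' into one shared transition matrix; the initial distribution is
#' re-estimated from expected chromosome-start occupancies. The
#' log-likelihood is non-decreasing over iterations; iteration stops when
#' its relative change drops below \code{tol} or after \code{maxIter}
#' rounds.
#'
#' @inheritParams forwardBackward
#' @param maxIter iteration cap (default 100).
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @return the updated \code{\linkS4class{HmmModel}}, with the
#'   per-iteration log-likelihood attached as attribute
#'   \code{"loglikTrace"}.
#' @export
baumWelch <- function(obs, model, maxIter = 100L, tol = 1e-6) {
  stopifnot(is(model, "HmmModel"))
  obsList <- .asObsList(obs)
  K <- model@nStates
  emiss <- lapply(obsList, .emissionMatrix, model = model)

  A <- model@transition
  pi <- model@initial
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    xiSum <- matrix(0, K, K)
    startOcc <- numeric(K)
    ll <- 0
    for (E in emiss) {
      fb <- .fbScaled(E, A, pi)
      xiSum <- xiSum + fb$xi
      startOcc <- startOcc + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)
    rs <- rowSums(xiSum)
    Anew <- A
    for (k in seq_len(K)) {
      if (rs[k] > 0) {
        Anew[k, ] <- xiSum[k, ] / rs[k]
      } else {
        warning(sprintf(
          "state %d has zero expected occupancy; keeping its transition row",
          k))
      }
    }
    A <- Anew
    pi <- startOcc / sum(startOcc)
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) / max(abs(trace[it]), 1) < tol)
      break
  }
  out <- HmmModel(A, model@logEmission, initial = pi,
                  stateNames = model@stateNames)
  attr(out, "loglikTrace") <- trace
  out
}

#' Decode per-bin state labels from posteriors
#'
#' Either maximum-posterior decoding (\code{rule = "max"}; ties broken
#' toward the lower state index) or the thresholding rule used for
#' two-state calling: bin labelled \code{state} when its posterior exceeds
#' \code{lambda}, otherwise the complementary label. With
#' \code{lambda = 0.5} in the two-state model the two rules coincide.
#'
#' @param posterior a \code{\linkS4class{PosteriorTrack}}.
#' @param rule \code{"max"} or \code{"threshold"}.
#' @param lambda posterior threshold in [0, 1) (threshold rule).
#' @param state index of the thresholded state (threshold rule; default 2,
#'   the modified state of the two-state model).
#' @return integer state labels (1-based), one per bin, with the state
#'   names attached as attribute \code{"stateNames"}.
#' @export
decodeStates <- function(posterior, rule = c("max", "threshold"),
                         lambda = 0.5, state = 2L) {
  stopifnot(is(posterior, "PosteriorTrack"))
  rule <- match.arg(rule)
  g <- posterior@gamma
  if (rule == "max") {
    lab <- max.col(g, ties.method = "first")
  } else {
    if (lambda < 0 || lambda >= 1) stop("'lambda' must lie in [0, 1)")
    if (state < 1L || state > ncol(g)) stop("invalid 'state' index")
    other <- g[, -state, drop = FALSE]
    otherIdx <- seq_len(ncol(g))[-state]
    lab <- ifelse(g[, state] > lambda, state,
                  otherIdx[max.col(other, ties.method = "first")])
  }
  structure(as.integer(lab), stateNames = posterior@stateNames)
}

#' Export posterior tracks to bedGraph
#'
#' Writes one bedGraph file per hidden state with the per-bin posterior
#' probability as the value.
#'
#' @param posterior a \code{\linkS4class{PosteriorTrack}} over genomic bins.
#' @param prefix output path prefix; files are named
#'   \code{<prefix>_<state>.bedGraph}.
#' @return the written paths, invisibly.
#' @export
exportPosteriorBedGraph <- function(posterior, prefix) {
  stopifnot(is(posterior, "PosteriorTrack"))
  paths <- character(0)
  for (k in seq_along(posterior@stateNames)) {
    gr <- posterior@bins
    S4Vectors::mcols(gr)$score <- posterior@gamma[, k]
    path <- sprintf("%s_%s.bedGraph", prefix,
                    gsub("[^A-Za-z0-9._-]", "-", posterior@stateNames[k]))
    rtracklayer::export(gr, path, format = "bedGraph")
    paths <- c(paths, path)
  }
  invisible(paths)
}
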