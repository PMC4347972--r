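#' @importFrom BiocGenerics counts
NULL

#' Accessors
#'
#' Slot accessors for the package's S4 classes.
#'
#' @param object,x an object of the documented class.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname accessors
#' @export
setMethod("bins", "BinnedTrack", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("bins", "PosteriorTrack", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("counts", "BinnedTrack", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setMethod("sampleId", "BinnedTrack", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("truncationValue", function(x) standardGeneric("truncationValue"))

#' @rdname accessors
#' @export
setMethod("truncationValue", "BinnedTrack", function(x) x@truncationValue)

#' @rdname accessors
#' @export
setGeneric("mixtureWeight", function(x) standardGeneric("mixtureWeight"))

#' @rdname accessors
#' @export
setMethod("mixtureWeight", "UnivariateMixture", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("component", function(x, which) standardGeneric("component"))

#' @rdname accessors
#' @export
setMethod("component", "UnivariateMixture", function(x, which) {
  stopifnot(which %in% c(0L, 1L))
  if (which == 0L) x@theta0 else x@theta1
})

#' @rdname accessors
#' @export
setMethod("component", "BivariateMixture", function(x, which) {
  x@components[[match.arg(which, c("00", "11", "10", "01"))]]
})

#' @rdname accessors
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))

#' @rdname accessors
#' @export
setMethod("loglikTrace", "UnivariateMixture", function(x) x@loglikTrace)

#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setMethod("nStates", "HmmModel", function(x) x@nStates)

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "HmmModel", function(x) x@transition)

#' @rdname accessors
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))

#' @rdname accessors
#' @export
setMethod("initialProbs", "HmmModel", function(x) x@initial)

#' @rdname accessors
#' @export
setGeneric("stateNames", function(x) standardGeneric("stateNames"))

#' @rdname accessors
#' @export
setMethod("stateNames", "HmmModel", function(x) x@stateNames)

#' @rdname accessors
#' @export
setMethod("stateNames", "PosteriorTrack", function(x) x@stateNames)

#' @rdname accessors
#' @export
setGeneric("posteriorMatrix", function(x) standardGeneric("posteriorMatrix"))

#' @rdname accessors
#' @export
setMethod("posteriorMatrix", "PosteriorTrack", function(x) x@gamma)

#' @rdname accessors
#' @export
setGeneric("trackLogLik", function(x) standardGeneric("trackLogLik"))

#' @rdname accessors
#' @export
setMethod("trackLogLik", "PosteriorTrack", function(x) x@loglik)

#' @rdname accessors
#' @export
setGeneric("copulaCorrelation", function(x) standardGeneric("copulaCorrelation"))

#' @rdname accessors
#' @export
setMethod("copulaCorrelation", "CopulaComponent", function(x) {
  s <- x@sigma
  s[1, 2] / sqrt(s[1, 1] * s[2, 2])
})

#' @rdname accessors
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))

#' @rdname accessors
#' @export
setMethod("mixingWeights", "BivariateMixture", function(x) x@gammaAb)

setMethod("length", "BinnedTrack", function(x) length(x@bins))

setMethod("show", "ZinbParams", function(object) {
  cat(sprintf("ZinbParams: r=%.4g p=%.4g beta=%.4g (mean %.3f)\n",
              object@r, object@p, object@beta, zinbMean(object)))
})

setMethod("show", "UnivariateMixture", function(object) {
  cat(sprintf("UnivariateMixture for sample '%s'\n", object@sampleId))
  cat(sprintf("  alpha (unmodified weight): %.4f\n", object@alpha))
  cat(sprintf("  theta0 (unmodified): r=%.4g p=%.4g beta=%.4g mean=%.3f\n",
              object@theta0@r, object@theta0@p, object@theta0@beta,
              zinbMean(object@theta0)))
  cat(sprintf("  theta1 (modified):   r=%.4g p=%.4g beta=%.4g mean=%.3f\n",
              object@theta1@r, object@theta1@p, object@theta1@beta,
              zinbMean(object@theta1)))
  if (length(object@loglikTrace))
    cat(sprintf("  EM: %d iterations, final loglik %.2f\n",
                length(object@loglikTrace),
                object@loglikTrace[length(object@loglikTrace)]))
})

setMethod("show", "BinnedTrack", function(object) {
  nchr <- length(unique(as.character(seqnames(object@bins))))
  cat(sprintf("BinnedTrack '%s': %d bins on %d chromosome(s)\n",
              object@sampleId, length(object@bins), nchr))
  if (length(object@counts))
    cat(sprintf("  counts: total %.0f, mean %.2f, max %d%s\n",
                sum(as.numeric(object@counts)), mean(object@counts),
                max(object@counts),
                if (is.na(object@truncationValue)) "" else
                  sprintf(" (truncated at %d)",
                          as.integer(object@truncationValue))))
})

setMethod("show", "HmmModel", function(object) {
  cat(sprintf("HmmModel with %d states: %s\n", object@nStates,
              paste(object@stateNames, collapse = ", ")))
  cat("  transition matrix:\n")
  m <- round(object@transition, 4)
  dimnames(m) <- list(object@stateNames, object@stateNames)
  print(m)
})

setMethod("show", "PosteriorTrack", function(object) {
  cat(sprintf("PosteriorTrack: %d bins x %d states, loglik %.2f\n",
              nrow(object@gamma), ncol(object@gamma), object@loglik))
})

setMethod("show", "CopulaComponent", function(object) {
  cat(sprintf(
    "CopulaComponent (a=%d, b=%d): rho=%.3f, support %d bins\n",
    object@a, object@b, copulaCorrelation(object), object@nSupport))
})

setMethod("show", "BivariateMixture", function(object) {
  cat("BivariateMixture with components (a,b):\n")
  for (nm in names(object@components)) {
    cmp <- object@components[[nm]]
    cat(sprintf("  %s: rho=%.3f weight=%.3f support=%d\n", nm,
                copulaCorrelation(cmp), object@gammaAb[[nm]], cmp@nSupport))
  }
})

setMethod("show", "CallingConfig", function(object) {
  cat("CallingConfig:\n")
  cat(sprintf("  binSize=%d lambda=%.2f confidence=%.2f truncQ=%.4f\n",
              object@binSize, object@lambda, object@confidence,
              object@truncationQuantile))
  cat(sprintf("  trainChrom=%s EM(max=%d,tol=%g) BW(max=%d,tol=%g) seed=%d\n",
              ifelse(is.na(object@trainChrom), "<largest>", object@trainChrom),
              object@emMaxIter, object@emTol, object@bwMaxIter, object@bwTol,
              object@seed))
})
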