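#' Region-calling configuration
#'
#' Bundles the tunable parameters of the calling workflows; see
#' \code{\linkS4class{CallingConfig}} for the meaning and rationale of each.
#'
#' @param binSize bin width in basepairs (default 1000).
#' @param lambda posterior threshold for modified calls (default 0.5, the
#'   maximal-probability state in the two-state model).
#' @param confidence covariance-subset posterior cutoff (default 0.9).
#' @param trainChrom chromosome used for the mixture fit (default: the
#'   largest chromosome present).
#' @param truncationQuantile genome-wide count quantile for truncation
#'   (default 0.999, i.e. the upper 0.1 percentile).
#' @param emMaxIter,emTol EM iteration cap and tolerance.
#' @param bwMaxIter,bwTol Baum-Welch iteration cap and tolerance.
#' @param minSupport minimum high-confidence bins per copula component.
#' @param seed integer seed recorded with the run.
#' @return a \code{\linkS4class{CallingConfig}}.
#' @export
callingConfig <- function(binSize = 1000L, lambda = 0.5, confidence = 0.9,
                          trainChrom = NA_character_,
                          truncationQuantile = 0.999, emMaxIter = 500L,
                          emTol = 1e-6, bwMaxIter = 100L, bwTol = 1e-6,
                          minSupport = 50L, seed = 1L) {
  new("CallingConfig", binSize = as.integer(binSize), lambda = lambda,
      confidence = confidence, trainChrom = as.character(trainChrom),
      truncationQuantile = truncationQuantile,
      emMaxIter = as.integer(emMaxIter), emTol = emTol,
      bwMaxIter = as.integer(bwMaxIter), bwTol = bwTol,
      minSupport = as.integer(minSupport), seed = as.integer(seed))
}

## Training chromosome: the configured one, or the largest present (the bin
## count stands in for chromosome length).
.trainChrom <- function(track, config) {
  chrom <- as.character(seqnames(bins(track)))
  if (!is.na(config@trainChrom)) {
    if (!config@trainChrom %in% chrom)
      stop(sprintf("training chromosome '%s' not present in the track",
                   config@trainChrom))
    return(config@trainChrom)
  }
  names(which.max(table(chrom)))
}

.univariateStateNames <- c("unmodified", "modified")
.bivariateStateNames <- c("unmod-both", "mod-both", "mod-A-only",
                          "mod-B-only")

## Fixed univariate emissions: the two mixture component densities (not
## weighted by alpha), floored before the log.
.univariateEmissions <- function(mixture) {
  list(function(o) .logFloor(dzinb(o, mixture@theta0)),
       function(o) .logFloor(dzinb(o, mixture@theta1)))
}

#' Single-sample region calling
#'
#' End-to-end segmentation of one binned ChIP-seq sample into modified and
#' unmodified domains: truncate extreme counts (if not already done), fit
#' the two-component ZINB mixture by EM on the training chromosome, use the
#' two components as fixed emission densities of a two-state HMM, estimate
#' transitions by Baum-Welch, compute genome-wide forward-backward
#' posteriors, call a bin modified when its posterior of the modified state
#' exceeds \code{lambda}, and merge consecutive same-label bins into
#' regions.
#'
#' @param track a \code{\linkS4class{BinnedTrack}}.
#' @param config a \code{\linkS4class{CallingConfig}}.
#' @return a list with elements \code{track} (the truncated track),
#'   \code{mixture}, \code{model}, \code{posterior}, \code{labels} and
#'   \code{regions} (a \code{GRanges}).
#' @export
callSingle <- function(track, config = callingConfig()) {
  stopifnot(is(track, "BinnedTrack"), is(config, "CallingConfig"))
  if (length(track) == 0L) stop("empty genome: track has no bins")
  if (is.na(truncationValue(track)))
    track <- truncateCounts(track, config@truncationQuantile)

  trainChrom <- .trainChrom(track, config)
  trainCounts <- counts(track)[as.character(seqnames(bins(track))) ==
                                 trainChrom]
  mixture <- tryCatch(
    fitZinbMixtureEM(trainCounts, maxIter = config@emMaxIter,
                     tol = config@emTol, sampleId = sampleId(track)),
    error = function(e)
      stop(sprintf("mixture fit failed for sample '%s' on %s: %s",
                   sampleId(track), trainChrom, conditionMessage(e)),
           call. = FALSE))

  model <- HmmModel(.defaultTransition(2L), .univariateEmissions(mixture),
                    stateNames = .univariateStateNames)
  model <- baumWelch(track, model, maxIter = config@bwMaxIter,
                     tol = config@bwTol)
  posterior <- forwardBackward(track, model)
  labels <- decodeStates(posterior, rule = "threshold",
                         lambda = config@lambda, state = 2L)
  regions <- assembleRegions(labels, bins(track), posterior)
  list(track = track, mixture = mixture, model = model,
       posterior = posterior, labels = labels, regions = regions)
}

#' Differential region calling between two samples
#'
#' End-to-end two-sample comparison: run the single-sample machinery on
#' each track to obtain univariate mixtures and posteriors, estimate the
#' four Gaussian-copula emission components from bins with high-confidence
#' univariate calls in both samples, build the four-state HMM (states
#' both-unmodified, both-modified, A-only-modified, B-only-modified) with
#' those fixed bivariate emissions, estimate transitions by Baum-Welch,
#' classify every bin by its maximal posterior state, and merge same-state
#' runs into regions. Differential regions are the A-only and B-only
#' states.
#'
#' @param trackA,trackB \code{\linkS4class{BinnedTrack}}s over identical
#'   bins.
#' @param config a \code{\linkS4class{CallingConfig}}.
#' @return a list with elements \code{trackA}, \code{trackB} (truncated),
#'   \code{singleA}, \code{singleB} (univariate results), \code{bivariate}
#'   (the \code{\linkS4class{BivariateMixture}}), \code{model},
#'   \code{posterior}, \code{labels}, \code{regions} and
#'   \code{differentialRegions}.
#' @export
callDifferential <- function(trackA, trackB, config = callingConfig()) {
  stopifnot(is(trackA, "BinnedTrack"), is(trackB, "BinnedTrack"))
  if (!identical(as.data.frame(bins(trackA)), as.data.frame(bins(trackB))))
    stop("trackA and trackB must share identical bins")

  singleA <- callSingle(trackA, config)
  singleB <- callSingle(trackB, config)

  bivariate <- estimateComponentCovariance(
    singleA$track, singleB$track, singleA$posterior, singleB$posterior,
    singleA$mixture, singleB$mixture, confidence = config@confidence,
    minSupport = config@minSupport)

  model <- HmmModel(.defaultTransition(4L),
                    lapply(bivariate@components, .copulaEmissionFun),
                    stateNames = .bivariateStateNames)

  chrom <- as.character(seqnames(bins(singleA$track)))
  obs <- lapply(split(seq_along(chrom), factor(chrom, unique(chrom))),
                function(i) cbind(counts(singleA$track)[i],
                                  counts(singleB$track)[i]))
  model <- baumWelch(obs, model, maxIter = config@bwMaxIter,
                     tol = config@bwTol)
  posterior <- forwardBackward(obs, model, bins = bins(singleA$track))
  labels <- decodeStates(posterior, rule = "max")
  regions <- assembleRegions(labels, bins(singleA$track), posterior)
  list(trackA = singleA$track, trackB = singleB$track,
       singleA = singleA, singleB = singleB, bivariate = bivariate,
       model = model, posterior = posterior, labels = labels,
       regions = regions,
       differentialRegions =
         regions[mcols(regions)$state %in% c("mod-A-only", "mod-B-only")])
}

#' Merge per-bin labels into regions
#'
#' Maximal runs of identical state labels within a chromosome become one
#' region carrying the state, the number of bins and the mean and maximum
#' posterior of its own state; runs never merge across chromosomes, so the
#' regions partition the binned genome.
#'
#' @param labels integer per-bin state labels, one per bin (e.g. from
#'   \code{\link{decodeStates}}).
#' @param genomeBins \code{GRanges} of the bins.
#' @param posterior optional \code{\linkS4class{PosteriorTrack}} supplying
#'   per-bin posteriors; without it the posterior summaries are set to 1.
#' @return a \code{GRanges} with metadata columns \code{state},
#'   \code{nBins}, \code{meanPosterior}, \code{maxPosterior}.
#' @export
assembleRegions <- function(labels, genomeBins, posterior = NULL) {
  if (length(labels) != length(genomeBins))
    stop("one label per bin required: got ", length(labels), " labels for ",
         length(genomeBins), " bins")
  stateNms <- attr(labels, "stateNames")
  if (is.null(stateNms)) stateNms <- paste0("state", seq_len(max(labels)))
  chrom <- as.character(seqnames(genomeBins))
  runs <- rle(paste(chrom, labels, sep = "\r"))
  lastBin <- cumsum(runs$lengths)
  firstBin <- lastBin - runs$lengths + 1L
  lab <- as.integer(labels[firstBin])
  gr <- GRanges(chrom[firstBin],
                IRanges(start = start(genomeBins)[firstBin],
                        end = end(genomeBins)[lastBin]))
  ownPost <- if (is.null(posterior)) rep(1, length(labels)) else
    posterior@gamma[cbind(seq_along(labels), as.integer(labels))]
  grpMean <- vapply(seq_along(firstBin), function(k)
    mean(ownPost[firstBin[k]:lastBin[k]]), numeric(1))
  grpMax <- vapply(seq_along(firstBin), function(k)
    max(ownPost[firstBin[k]:lastBin[k]]), numeric(1))
  mcols(gr) <- S4Vectors::DataFrame(
    state = factor(stateNms[lab], levels = stateNms),
    nBins = runs$lengths, meanPosterior = grpMean, maxPosterior = grpMax)
  sl <- seqlengths(genomeBins)
  if (!anyNA(sl)) GenomeInfoDb::seqlengths(gr) <- sl[seqlevels(gr)]
  gr
}

#' Export called regions to BED and GFF3
#'
#' Writes one BED file per state (score column = 1000 x mean posterior of
#' the region's own state, clipped to [0, 1000]) and one combined GFF3 file
#' with the state and posterior summaries in the attributes.
#'
#' @param regions region \code{GRanges} from \code{\link{assembleRegions}}.
#' @param prefix output path prefix; files are named
#'   \code{<prefix>_<state>.bed} and \code{<prefix>.gff3}.
#' @return the written paths, invisibly.
#' @export
exportRegions <- function(regions, prefix) {
  paths <- character(0)
  states <- levels(mcols(regions)$state)
  for (st in states) {
    sub <- regions[mcols(regions)$state == st]
    gr <- GRanges(seqnames(sub), IRanges(start(sub), end(sub)))
    mcols(gr)$name <- as.character(mcols(sub)$state)
    mcols(gr)$score <- pmin(pmax(round(1000 * mcols(sub)$meanPosterior), 0),
                            1000)
    path <- sprintf("%s_%s.bed", prefix, gsub("[^A-Za-z0-9._-]", "-", st))
    rtracklayer::export(gr, path, format = "BED")
    paths <- c(paths, path)
  }
  gff <- GRanges(seqnames(regions), IRanges(start(regions), end(regions)))
  mcols(gff)$source <- "broadHMM"
  mcols(gff)$type <- "region"
  mcols(gff)$score <- mcols(regions)$meanPosterior
  mcols(gff)$state <- as.character(mcols(regions)$state)
  mcols(gff)$nBins <- mcols(regions)$nBins
  mcols(gff)$maxPosterior <- mcols(regions)$maxPosterior
  gffPath <- paste0(prefix, ".gff3")
  rtracklayer::export(gff, gffPath, format = "gff3")
  invisible(c(paths, gffPath))
}

#' Write a run log
#'
#' Plain-text echo of the configuration, the Baum-Welch and EM
#' log-likelihood traces and the copula component support sizes, for
#' provenance alongside the exported tracks.
#'
#' @param path output file path.
#' @param config the \code{\linkS4class{CallingConfig}} used.
#' @param result the list returned by \code{\link{callSingle}} or
#'   \code{\link{callDifferential}}.
#' @return \code{path}, invisibly.
#' @export
writeRunLog <- function(path, config, result) {
  con <- file(path, "w")
  on.exit(close(con))
  out <- function(...) cat(..., "\n", sep = "", file = con)
  out("# broadHMM run log")
  out(sprintf("binSize\t%d", config@binSize))
  out(sprintf("lambda\t%g", config@lambda))
  out(sprintf("confidence\t%g", config@confidence))
  out(sprintf("truncationQuantile\t%g", config@truncationQuantile))
  out(sprintf("trainChrom\t%s",
              ifelse(is.na(config@trainChrom), "<largest>",
                     config@trainChrom)))
  out(sprintf("seed\t%d", config@seed))
  writeTrace <- function(tag, tr)
    out(sprintf("%s\t%s", tag, paste(format(tr, digits = 10),
                                     collapse = ",")))
  if (!is.null(result$mixture))
    writeTrace("emLoglikTrace", loglikTrace(result$mixture))
  if (!is.null(result$singleA)) {
    writeTrace("emLoglikTraceA", loglikTrace(result$singleA$mixture))
    writeTrace("emLoglikTraceB", loglikTrace(result$singleB$mixture))
    for (nm in names(result$bivariate@components))
      out(sprintf("componentSupport.%s\t%d", nm,
                  result$bivariate@components[[nm]]@nSupport))
  }
  if (!is.null(attr(result$model, "loglikTrace")))
    writeTrace("bwLoglikTrace", attr(result$model, "loglikTrace"))
  out(sprintf("loglik\t%.6f", trackLogLik(result$posterior)))
  invisible(path)
}
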