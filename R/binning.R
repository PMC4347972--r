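#' Tile a genome into fixed-width bins
#'
#' Partitions each chromosome into ordered, non-overlapping windows of
#' \code{binSize} basepairs; the last window of a chromosome is truncated at
#' the chromosome end, so all bins except possibly the last share one width.
#'
#' @param seqlengths named integer vector of chromosome lengths (basepairs).
#' @param binSize bin width in basepairs (default 1000).
#' @return a \code{GRanges} of bins with seqlengths set, ordered by
#'   chromosome then start.
#' @examples
#' genomeBins(c(chrA = 2500), binSize = 1000)
#' @export
genomeBins <- function(seqlengths, binSize = 1000) {
  if (length(seqlengths) == 0L) stop("empty chromosome sizes table")
  if (binSize <= 0) stop("'binSize' must be > 0")
  if (is.null(names(seqlengths)) || anyNA(seqlengths) || any(seqlengths < 1))
    stop("'seqlengths' must be a named vector of positive lengths")
  bins <- tileGenome(seqlengths, tilewidth = binSize,
                     cut.last.tile.in.chrom = TRUE)
  unname(bins)
}

#' Construct a binned track
#'
#' Low-level constructor pairing genome bins with per-bin counts.
#'
#' @param bins a \code{GRanges} of bins as made by \code{\link{genomeBins}}.
#' @param counts one non-negative integer per bin.
#' @param sampleId sample identifier.
#' @param truncationValue the count ceiling if truncation was applied,
#'   \code{NA} otherwise.
#' @return a \code{\linkS4class{BinnedTrack}}.
#' @export
BinnedTrack <- function(bins, counts, sampleId = "sample",
                        truncationValue = NA_real_) {
  new("BinnedTrack", bins = bins, counts = as.integer(counts),
      sampleId = as.character(sampleId),
      truncationValue = as.numeric(truncationValue))
}

#' Count read start positions in genome bins
#'
#' Bins the genome into fixed-width windows and counts, for every window, the
#' reads whose start position falls inside it. Each read contributes exactly
#' once, at its leftmost aligned coordinate (regardless of strand, unless
#' \code{strandAware5prime}). Reads on chromosomes absent from the sizes
#' table are tallied and reported with a warning, never silently dropped.
#'
#' @param reads a \code{GRanges} (or \code{GAlignments}) of aligned reads,
#'   e.g. from \code{\link{readBamReads}} or \code{\link{readBedReads}}.
#' @param seqlengths named vector of chromosome lengths; chromosomes of
#'   \code{reads} must appear here to be counted.
#' @param binSize bin width in basepairs (default 1000).
#' @param sampleId sample identifier stored on the track.
#' @param strandAware5prime if \code{TRUE}, reads on the minus strand are
#'   counted at their rightmost coordinate (their 5' end) instead of the
#'   leftmost; off by default.
#' @param dedup if \code{TRUE}, drop reads with identical
#'   (chromosome, position, strand) before counting — a convenience filter
#'   for libraries where PCR duplicates were not removed upstream.
#' @return a \code{\linkS4class{BinnedTrack}} (untruncated). The number of
#'   reads skipped because their chromosome is missing from
#'   \code{seqlengths} is attached as attribute \code{"skippedReads"}.
#' @export
binReads <- function(reads, seqlengths, binSize = 1000, sampleId = "sample",
                     strandAware5prime = FALSE, dedup = FALSE) {
  if (length(seqlengths) == 0L) stop("empty chromosome sizes table")
  if (binSize <= 0) stop("'binSize' must be > 0")
  reads <- GRanges(reads)
  bins <- genomeBins(seqlengths, binSize)

  chrom <- as.character(seqnames(reads))
  pos <- ifelse(strandAware5prime &
                  as.character(BiocGenerics::strand(reads)) == "-",
                end(reads), start(reads))
  strnd <- as.character(BiocGenerics::strand(reads))

  known <- chrom %in% names(seqlengths)
  nSkipped <- sum(!known)
  if (nSkipped > 0L) {
    bad <- unique(chrom[!known])
    warning(sprintf(
      "%d read(s) on %d chromosome(s) absent from the sizes table skipped: %s",
      nSkipped, length(bad), paste(utils::head(bad, 5), collapse = ", ")))
  }
  chrom <- chrom[known]; pos <- pos[known]; strnd <- strnd[known]

  inRange <- pos >= 1L & pos <= seqlengths[chrom]
  if (any(!inRange)) {
    warning(sprintf("%d read position(s) beyond chromosome ends skipped",
                    sum(!inRange)))
    chrom <- chrom[inRange]; pos <- pos[inRange]; strnd <- strnd[inRange]
  }

  if (dedup) {
    keep <- !duplicated(paste(chrom, pos, strnd, sep = "\r"))
    chrom <- chrom[keep]; pos <- pos[keep]
  }

  nBinsPerChrom <- ceiling(seqlengths / binSize)
  offset <- c(0, cumsum(nBinsPerChrom))[seq_along(seqlengths)]
  names(offset) <- names(seqlengths)
  idx <- offset[chrom] + (pos - 1L) %/% binSize + 1L
  cnt <- tabulate(idx, nbins = length(bins))

  out <- BinnedTrack(bins, cnt, sampleId = sampleId)
  attr(out, "skippedReads") <- nSkipped
  out
}

#' Truncate extreme bin counts at an upper quantile
#'
#' Caps per-bin read counts at the genome-wide empirical quantile of the
#' sample's counts (nearest-rank, \code{type = 1}, so the cap is an observed
#' integer count), the standard guard against artefact regions with extreme
#' read pile-ups and against vanishing emission probabilities downstream.
#' The default caps at the upper 0.1 percentile (quantile 0.999).
#'
#' Idempotent: truncating an already-truncated track changes nothing.
#'
#' @param track a \code{\linkS4class{BinnedTrack}}.
#' @param upperQuantile quantile in (0, 1] at which to cap (default 0.999).
#' @return a new \code{\linkS4class{BinnedTrack}} with capped counts and
#'   \code{truncationValue} set; the input is not modified.
#' @export
truncateCounts <- function(track, upperQuantile = 0.999) {
  stopifnot(is(track, "BinnedTrack"))
  if (upperQuantile <= 0 || upperQuantile > 1)
    stop("'upperQuantile' must lie in (0, 1]")
  if (length(track@counts) == 0L) stop("track has no counts")
  q <- floor(stats::quantile(track@counts, probs = upperQuantile,
                             type = 1, names = FALSE))
  BinnedTrack(track@bins, pmin(track@counts, as.integer(q)),
              sampleId = track@sampleId, truncationValue = q)
}

#' Read aligned reads from a BAM file
#'
#' Imports uniquely-mapping aligned reads: unmapped records are dropped and
#' reads with mapping quality below \code{mapqMin} are skipped (multimappers
#' typically carry MAPQ 0).
#'
#' @param path BAM file path.
#' @param mapqMin minimum mapping quality (default 1).
#' @return a \code{GRanges} of reads.
#' @export
readBamReads <- function(path, mapqMin = 1L) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = as.integer(mapqMin))
  GRanges(GenomicAlignments::readGAlignments(path, param = param))
}

#' Read aligned reads from a BED file
#'
#' BED input is taken as pre-filtered for unique mappers.
#'
#' @param path BED file path (3-6 columns).
#' @return a \code{GRanges} of reads.
#' @export
readBedReads <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a chromosome-sizes table
#'
#' Two-column whitespace-separated text file: chromosome name, length.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop("empty chromosome sizes table")
  stats::setNames(tab$length, tab$chrom)
}

#' Write binned tracks to a count table
#'
#' Tab-separated interchange format with a single header line:
#' \code{chrom  start  end  count_<idA> [count_<idB> ...]}, coordinates
#' 0-based half-open (BED-like). All tracks must share identical bins.
#'
#' @param tracks a \code{\linkS4class{BinnedTrack}} or list of tracks over
#'   identical bins.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(tracks, path) {
  if (is(tracks, "BinnedTrack")) tracks <- list(tracks)
  b <- bins(tracks[[1]])
  for (tr in tracks[-1])
    if (!identical(as.data.frame(bins(tr)), as.data.frame(b)))
      stop("all tracks must share identical bins")
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b))
  for (tr in tracks) df[[paste0("count_", sampleId(tr))]] <- counts(tr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load binned tracks from a count table
#'
#' Reads the tab-separated format written by \code{\link{writeCountTable}}:
#' columns \code{chrom}, \code{start}, \code{end} (0-based half-open), then
#' one count column per sample. Bins must be contiguous and of constant
#' width within each chromosome (the last bin of a chromosome may be
#' shorter); the bin size is inferred from the first row.
#'
#' @param path input file path.
#' @return a list of \code{\linkS4class{BinnedTrack}}s, one per count
#'   column, sharing one set of bins; sample ids are taken from the column
#'   names (a \code{count_} prefix is stripped).
#' @export
loadCountTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)[1:3]))
    stop("count table must start with columns chrom, start, end")
  countCols <- setdiff(names(df), need)
  if (length(countCols) == 0L) stop("count table has no count columns")
  if (nrow(df) == 0L) stop("count table is empty")

  binSize <- df$end[1] - df$start[1]
  if (binSize <= 0) stop("invalid bin width in first row")

  chromRle <- rle(df$chrom)
  if (any(duplicated(chromRle$values)))
    stop("rows of each chromosome must be grouped together")
  lastRow <- cumsum(chromRle$lengths)
  firstRow <- lastRow - chromRle$lengths + 1L

  for (k in seq_along(chromRle$values)) {
    rows <- firstRow[k]:lastRow[k]
    s <- df$start[rows]; e <- df$end[rows]
    if (s[1] != 0)
      stop(sprintf("row %d: first bin of %s must start at 0",
                   rows[1], chromRle$values[k]))
    if (length(rows) > 1L) {
      gap <- which(s[-1] != e[-length(e)])
      if (length(gap))
        stop(sprintf("row %d: gap or overlap between consecutive bins on %s",
                     rows[gap[1] + 1L], chromRle$values[k]))
      w <- e - s
      bad <- which(w[-length(w)] != binSize)
      if (length(bad))
        stop(sprintf("row %d: non-constant bin width on %s",
                     rows[bad[1]], chromRle$values[k]))
      if (w[length(w)] > binSize)
        stop(sprintf("row %d: last bin wider than bin size on %s",
                     rows[length(rows)], chromRle$values[k]))
    }
  }

  for (cc in countCols) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(v < 0) || any(v != floor(v)))
      stop(sprintf("column '%s' must contain non-negative integers", cc))
  }

  seqlen <- stats::setNames(df$end[lastRow], chromRle$values)
  b <- genomeBins(seqlen, binSize)
  stopifnot(length(b) == nrow(df))
  lapply(countCols, function(cc)
    BinnedTrack(b, as.integer(df[[cc]]), sampleId = sub("^count_", "", cc)))
}
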