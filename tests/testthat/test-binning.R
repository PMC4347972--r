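test_that("read starts are counted once into half-open bins", {
  sl <- c(chrA = 3000)
  # leftmost coordinates 11, 991, 1001 (1-based): two in the first
  # kilobase, one at the start of the second
  reads <- GRanges("chrA", IRanges(start = c(11, 991, 1001), width = 36))
  tr <- binReads(reads, sl, binSize = 1000)
  expect_identical(counts(tr), c(2L, 1L, 0L))
  expect_identical(width(bins(tr)), rep(1000L, 3))

  # bin-edge behaviour: 1-based position 1000 is the last basepair of the
  # first bin, 1001 the first of the second
  tr2 <- binReads(GRanges("chrA", IRanges(start = c(1000, 1001), width = 1)),
                  sl, binSize = 1000)
  expect_identical(counts(tr2), c(1L, 1L, 0L))
})

test_that("empty input yields all-zero counts over ceil(length/binSize) bins", {
  tr <- binReads(GRanges(), c(chrA = 2500), binSize = 1000)
  expect_identical(counts(tr), c(0L, 0L, 0L))
  expect_identical(width(bins(tr)), c(1000L, 1000L, 500L))
})

test_that("binning conserves reads and is invariant to input order", {
  set.seed(101)
  n <- 10000L
  pos <- sample.int(1e6, n, replace = TRUE)
  reads <- GRanges("chr1", IRanges(start = pos, width = 36))
  tr <- binReads(reads, c(chr1 = 1e6), binSize = 1000)
  expect_identical(sum(counts(tr)), n)
  expect_equal(mean(counts(tr)), 10)
  shuf <- reads[sample(length(reads))]
  expect_identical(counts(binReads(shuf, c(chr1 = 1e6), 1000)), counts(tr))
})

test_that("reads on unknown chromosomes are reported, not silently dropped", {
  reads <- GRanges(c("chrA", "chrU", "chrU"),
                   IRanges(start = c(5, 5, 10), width = 10))
  expect_warning(tr <- binReads(reads, c(chrA = 1000), binSize = 1000),
                 "absent from the sizes table")
  expect_identical(sum(counts(tr)), 1L)
  expect_identical(attr(tr, "skippedReads"), 2L)
})

test_that("binning rejects invalid genome specifications", {
  reads <- GRanges("chrA", IRanges(1, 10))
  expect_error(binReads(reads, integer(0)), "empty chromosome sizes")
  expect_error(binReads(reads, c(chrA = 1000), binSize = 0), "binSize")
  expect_error(genomeBins(c(chrA = 1000), binSize = -5), "binSize")
})

test_that("strand-aware counting moves minus-strand reads to their 5' end", {
  sl <- c(chrA = 3000)
  reads <- GRanges("chrA", IRanges(start = 980, width = 36), strand = "-")
  expect_identical(counts(binReads(reads, sl, 1000)), c(1L, 0L, 0L))
  expect_identical(
    counts(binReads(reads, sl, 1000, strandAware5prime = TRUE)),
    c(0L, 1L, 0L))
})

test_that("optional duplicate filter collapses identical (chrom,pos,strand)", {
  reads <- GRanges("chrA", IRanges(start = c(11, 11, 11, 500), width = 36),
                   strand = c("+", "+", "-", "+"))
  tr <- binReads(reads, c(chrA = 1000), 1000, dedup = TRUE)
  expect_identical(counts(tr), 3L)  # +11 and -11 kept, one +11 dropped
})

test_that("count truncation caps at the nearest-rank genome-wide quantile", {
  b <- genomeBins(c(chrA = 1e6), 1000)

  # all counts equal: the quantile equals every value, nothing changes
  tr <- BinnedTrack(b, rep(5L, length(b)))
  expect_identical(counts(truncateCounts(tr)), rep(5L, length(b)))

  # 999 ones and a single 1000: sort-based nearest-rank oracle
  cnt <- c(rep(1L, 999), 1000L)
  tr2 <- BinnedTrack(genomeBins(c(chrA = 1e6), 1000), cnt)
  srt <- sort(cnt)
  qOracle <- srt[ceiling(0.999 * length(cnt))]
  out <- truncateCounts(tr2, 0.999)
  expect_identical(max(counts(out)), qOracle)
  expect_identical(counts(out)[1000], qOracle)
  expect_identical(counts(out)[1:999], cnt[1:999])
  expect_identical(truncationValue(out), as.numeric(qOracle))
  # the input track is untouched
  expect_identical(max(counts(tr2)), 1000L)

  # degenerate all-zero input passes through
  tr3 <- BinnedTrack(genomeBins(c(chrA = 3000), 1000), c(0L, 0L, 0L))
  expect_identical(counts(truncateCounts(tr3, 0.999)), c(0L, 0L, 0L))
})

test_that("truncation is idempotent and validates its quantile", {
  set.seed(5)
  b <- genomeBins(c(chrA = 2e5), 1000)
  tr <- BinnedTrack(b, rpois(length(b), 4) + rbinom(length(b), 1, 0.01) * 50L)
  once <- truncateCounts(tr, 0.99)
  twice <- truncateCounts(once, 0.99)
  expect_identical(counts(twice), counts(once))
  expect_error(truncateCounts(tr, 0), "upperQuantile")
  expect_error(truncateCounts(tr, 1.2), "upperQuantile")
})

test_that("count tables round-trip exactly and share one set of bins", {
  set.seed(21)
  spec <- simulationSpec(nChromosomes = 2, binsPerChromosome = 40, seed = 3)
  sim <- simulateBivariate(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(list(sim$trackA, sim$trackB), path)
  tracks <- loadCountTable(path)
  expect_length(tracks, 2L)
  expect_identical(counts(tracks[[1]]), counts(sim$trackA))
  expect_identical(counts(tracks[[2]]), counts(sim$trackB))
  expect_identical(sampleId(tracks[[1]]), sampleId(sim$trackA))
  expect_identical(as.data.frame(bins(tracks[[1]])),
                   as.data.frame(bins(tracks[[2]])))
  expect_identical(as.data.frame(bins(tracks[[1]])),
                   as.data.frame(bins(sim$trackA)))
})

test_that("malformed count tables are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tcount_s1",
               "chrA\t0\t1000\t3",
               "chrA\t2000\t3000\t1"), path)
  expect_error(loadCountTable(path), "row 2.*gap")

  writeLines(c("chrom\tstart\tend\tcount_s1",
               "chrA\t0\t1000\t3",
               "chrA\t1000\t2000\t-1"), path)
  expect_error(loadCountTable(path), "non-negative integers")

  writeLines(c("chrom\tstart\tend\tcount_s1",
               "chrA\t0\t1000\t3",
               "chrA\t1000\t2000\t1.5"), path)
  expect_error(loadCountTable(path), "non-negative integers")
})

test_that("BAM import keeps only uniquely mapping reads above the MAPQ cutoff", {
  samPath <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrA\tLN:3000",
    "r1\t0\tchrA\t11\t30\t36M\t*\t0\t0\t*\t*",
    "r2\t16\tchrA\t991\t30\t36M\t*\t0\t0\t*\t*",
    "r3\t0\tchrA\t1001\t0\t36M\t*\t0\t0\t*\t*"), samPath)
  bamPath <- Rsamtools::asBam(samPath, overwrite = TRUE)
  reads <- readBamReads(bamPath, mapqMin = 1)
  expect_length(reads, 2L)  # MAPQ-0 multimapper dropped
  tr <- binReads(reads, c(chrA = 3000), 1000)
  expect_identical(counts(tr), c(2L, 0L, 0L))
})

test_that("BED reads import with 1-based starts", {
  bedPath <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t10\t46\tr1\t0\t+",
               "chrA\t990\t1026\tr2\t0\t-"), bedPath)
  reads <- readBedReads(bedPath)
  expect_identical(start(reads), c(11L, 991L))
  tr <- binReads(reads, c(chrA = 3000), 1000)
  expect_identical(counts(tr), c(2L, 0L, 0L))
})

test_that("chromosome sizes files parse to a named vector", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t100000", "chr2\t50000"), path)
  sl <- readChromSizes(path)
  expect_identical(sl, c(chr1 = 1e5, chr2 = 5e4))
})
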