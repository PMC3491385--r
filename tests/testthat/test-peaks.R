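# Minimal KSProfile with chosen p-values on a regular grid.
profileFromP <- function(p, chrom = rep("chr1", length(p)), spacing = 100,
                         plen = 50) {
  n <- length(p)
  start0 <- (seq_len(n) - 1L) * spacing
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = start0 + plen))
  mcols(gr) <- DataFrame(midpoint = start0 + plen / 2, ratio = 0,
                         d_statistic = 0, p_value = p,
                         n_window = 8L, no_score = FALSE)
  new("KSProfile", scores = sort(gr), windowBp = 750,
      background = "exclude_window", params = list())
}

test_that("peaks are maximal runs of >= 2 qualifying probes", {
  pk <- callPeaks(profileFromP(c(0.5, 0.005, 0.008, 0.9)))
  expect_equal(length(pk), 1L)
  expect_equal(mcols(pk)$n_probes, 2L)
  expect_equal(mcols(pk)$min_p, 0.005)
  expect_equal(start(pk) - 1L, 100L)   # first member's start
  expect_equal(end(pk), 250L)          # last member's end

  # isolated qualifying probe: no peak
  expect_equal(length(callPeaks(profileFromP(c(0.5, 0.001, 0.5)))), 0L)
})

test_that("runs break across chromosomes and large gaps", {
  p <- rep(0.001, 4)
  pk <- callPeaks(profileFromP(p, chrom = c("chr1", "chr1", "chr2",
                                            "chr2")))
  expect_equal(length(pk), 2L)

  # same chromosome, but a tiling gap beyond maxGapBp splits the run
  gr_p <- c(0.001, 0.001, 0.001, 0.001)
  prof <- profileFromP(gr_p)
  mid <- mcols(scoreRanges(prof))$midpoint
  gr <- scoreRanges(prof)
  shift_idx <- 3:4
  gr[shift_idx] <- GenomicRanges::shift(gr[shift_idx], 5000)
  mcols(gr)$midpoint[shift_idx] <- mid[shift_idx] + 5000
  prof2 <- new("KSProfile", scores = gr, windowBp = 750,
               background = "exclude_window", params = list())
  expect_equal(length(callPeaks(prof2, maxGapBp = 1000)), 2L)
  expect_equal(length(callPeaks(prof2, maxGapBp = Inf)), 1L)
})

test_that("peak calling equals the brute-force run scanner", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(20:120, 1)
    p <- 10^runif(n, -4, 0)
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    prof <- profileFromP(p, chrom = chrom)
    gr <- scoreRanges(prof)
    got <- peaksAsDf(callPeaks(prof))
    want <- brutePeaks(as.character(seqnames(gr)), mcols(gr)$midpoint,
                       mcols(gr)$p_value, start(gr) - 1L, end(gr))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("promoter methylation needs a peak overlap in both replicates", {
  ann <- promoterAnnotation("g1", "chr1", 10000, "+")
  peak_in <- GRanges("chr1", IRanges(9501, 9800))   # inside [-1000, 0)
  none <- GRanges()
  expect_false(promoterMethylated(ann, peak_in, none, c(-1000, 0))[["g1"]])
  expect_true(promoterMethylated(ann, peak_in, peak_in,
                                 c(-1000, 0))[["g1"]])
})

test_that("methylation calls match an interval-intersection oracle", {
  set.seed(55)
  n <- 300
  tss <- seq(20000, by = 40000, length.out = n)
  strand <- rep(c("+", "-"), length.out = n)
  ann <- promoterAnnotation(sprintf("g%03d", 1:n), "chr1", tss, strand)
  randPeaks <- function() {
    k <- 150
    anchor <- sample(tss, k, replace = TRUE)
    off <- sample(-6000:6000, k, replace = TRUE)
    s <- anchor + off
    GRanges("chr1", IRanges(start = s + 1, width = sample(200:2000, k,
                                                          replace = TRUE)))
  }
  pk1 <- randPeaks(); pk2 <- randPeaks()
  win <- c(-5000, 1000)
  got <- promoterMethylated(ann, pk1, pk2, win)
  for (g in seq_len(n)) {
    # expected: strand-aware genomic window, 0-based half-open overlap
    lo <- if (strand[g] == "-") tss[g] - win[2] else tss[g] + win[1]
    hi <- if (strand[g] == "-") tss[g] - win[1] else tss[g] + win[2]
    hits <- function(pk) any(pmax(start(pk) - 1, lo) < pmin(end(pk), hi))
    expect_identical(unname(got[g]), hits(pk1) && hits(pk2))
  }
})

test_that("methylation location categories follow the window geometry", {
  ann <- promoterAnnotation("g1", "chr1", 10000, "+")
  up_peak <- GRanges("chr1", IRanges(9101, 9400))     # rel [-900, -600)
  span_peak <- GRanges("chr1", IRanges(9801, 10300))  # rel [-200, +300)
  expect_equal(as.character(
    classifyMethylationLocation(ann, up_peak, up_peak)[["g1"]]),
    "up_only")
  expect_equal(as.character(
    classifyMethylationLocation(ann, span_peak, span_peak)[["g1"]]),
    "tss_both")
  expect_equal(as.character(
    classifyMethylationLocation(ann, GRanges(), GRanges())[["g1"]]),
    "none")
})

test_that("hypomethylation requires every window probe at the floor", {
  ann <- promoterAnnotation("g1", "chr1", 1000, "+")
  mkprof <- function(p) {
    n <- length(p)
    start0 <- seq(0, by = 100, length.out = n)   # midpoints 25..  in [0,1000)
    gr <- GRanges("chr1", IRanges(start0 + 1L, start0 + 50L))
    mcols(gr) <- DataFrame(midpoint = start0 + 25, ratio = 0,
                           d_statistic = 0, p_value = p, n_window = 8L,
                           no_score = FALSE)
    new("KSProfile", scores = gr, windowBp = 750,
        background = "exclude_window", params = list())
  }
  all_high <- mkprof(rep(1, 8))
  one_low <- mkprof(c(rep(1, 4), 0.5, rep(1, 3)))
  expect_equal(as.character(callHypomethylated(ann, all_high, all_high,
                                               c(-1000, 0))[["g1"]]),
               "yes")
  expect_equal(as.character(callHypomethylated(ann, all_high, one_low,
                                               c(-1000, 0))[["g1"]]),
               "no")
  # too few probes in the window: no_call, never a vacuous yes
  sparse <- mkprof(rep(1, 2))
  expect_equal(as.character(callHypomethylated(ann, sparse, sparse,
                                               c(-1000, 0),
                                               minProbesPresent = 3L)[["g1"]]),
               "no_call")
})

test_that("simulated data keep methylated and hypomethylated calls disjoint
           and monotone in the probe cutoff", {
  cfg <- simulationConfig(nGenes = 120, seed = 19)
  base <- simulatePromoterSequences(cfg)
  reps <- simulateTilingExperiment(cfg, base$truth, "mbt")
  pr1 <- ksProbeScores(normalizeCenter(reps$rep1))
  pr2 <- ksProbeScores(normalizeCenter(reps$rep2))
  pk1 <- callPeaks(pr1); pk2 <- callPeaks(pr2)
  calls <- callMethylationTable(base$annotation, pk1, pk2, pr1, pr2,
                                stage = "mbt")
  expect_equal(sum(calls$hypomethylated == "yes" &
                     calls$category %in% c("up_only", "tss_both")), 0L)

  pk1s <- callPeaks(pr1, pCutoff = 0.001)
  pk2s <- callPeaks(pr2, pCutoff = 0.001)
  strict <- promoterMethylated(base$annotation, pk1s, pk2s)
  loose <- promoterMethylated(base$annotation, pk1, pk2)
  expect_true(all(!strict | loose))
})
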