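#' Call methylation peaks from a KS profile
#'
#' A peak is every maximal run of consecutive probes (array order within a
#' chromosome) whose KS p-value is at or below `pCutoff`, of length at
#' least `minProbes`.  Runs are additionally broken where the midpoint gap
#' between neighbouring probes exceeds `maxGapBp`, so that runs never leap
#' across untiled territory.  The peak interval spans the first member's
#' start to the last member's end.
#'
#' @param profile a [KSProfile-class] (coordinate-sorted, as produced by
#'   [ksProbeScores()]).
#' @param pCutoff probe p-value cutoff (default 0.01).
#' @param minProbes minimum qualifying run length (default 2).
#' @param maxGapBp maximum midpoint gap inside a run (default 1000);
#'   `Inf` disables gap breaking.
#' @return `GRanges` of peaks with metadata `n_probes` and `min_p`.
#' @export
callPeaks <- function(profile, pCutoff = 0.01, minProbes = 2L,
                      maxGapBp = 1000) {
  stopifnot(is(profile, "KSProfile"))
  gr <- scoreRanges(profile)
  if (length(gr) == 0L)
    return(GRanges(n_probes = integer(), min_p = numeric()))
  p <- mcols(gr)$p_value
  mid <- mcols(gr)$midpoint
  chr <- as.character(seqnames(gr))
  q <- p <= pCutoff
  # run id increments at: non-qualifying probe, chromosome change, big gap
  brk <- c(TRUE, chr[-1] != chr[-length(chr)] |
                 (mid[-1] - mid[-length(mid)]) > maxGapBp)
  run <- cumsum(brk | !q)          # constant over contiguous qualifying runs
  keep <- which(q)
  if (!length(keep))
    return(GRanges(n_probes = integer(), min_p = numeric()))
  runs <- split(keep, run[keep])
  sizes <- lengths(runs)
  runs <- runs[sizes >= minProbes]
  if (!length(runs))
    return(GRanges(n_probes = integer(), min_p = numeric()))
  first <- vapply(runs, `[`, integer(1), 1L)
  last <- vapply(runs, function(i) i[length(i)], integer(1))
  pk <- GRanges(chr[first], IRanges(start(gr)[first], end(gr)[last]),
                n_probes = unname(lengths(runs)),
                min_p = unname(vapply(runs, function(i) min(p[i]),
                                      numeric(1))))
  sort(pk)
}

#' Write peaks as BED6
#'
#' BED score is `-10 * log10(min_p)` capped at 1000; coordinates are
#' 0-based half-open as BED requires.
#'
#' @param peaks peak `GRanges` from [callPeaks()].
#' @param path output file.
#' @param trackName BED name field prefix.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(peaks, path, trackName = "peak") {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = paste0(trackName, "_", seq_along(peaks)),
                   score = pmin(1000, round(-10 * log10(
                     pmax(mcols(peaks)$min_p, 1e-100)))),
                   strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Genomic GRanges of the strand-aware TSS-relative window [lo, hi) for each
# promoter.  In 0-based half-open terms the + strand window is
# [tss + lo, tss + hi) and the - strand window is its reflection
# [tss - hi, tss - lo).
promoterWindowRanges <- function(ann, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  tss <- mcols(ann)$tss
  minus <- as.character(strand(ann)) == "-"
  start0 <- ifelse(minus, tss - window[2], tss + window[1])
  end0 <- ifelse(minus, tss - window[1], tss + window[2])
  out <- GRanges(seqnames(ann), IRanges(start = start0 + 1, end = end0),
                 strand = strand(ann), gene_id = mcols(ann)$gene_id)
  names(out) <- names(ann)
  out
}

#' Replicate-consistent promoter methylation call
#'
#' A promoter is scored methylated when its TSS-relative window, mapped to
#' genomic coordinates strand-aware, overlaps at least one peak in *both*
#' MeDIP replicates (overlap = non-empty half-open intersection).
#'
#' @param ann promoter annotation `GRanges` ([promoterAnnotation()]); may
#'   contain one or many genes.
#' @param peaks_rep1,peaks_rep2 peak `GRanges` from [callPeaks()] for the
#'   two replicates of one stage.
#' @param window TSS-relative window `c(lo, hi)` (default the -5 kb/+1 kb
#'   analysis region).
#' @return named logical vector, one call per gene.
#' @export
promoterMethylated <- function(ann, peaks_rep1, peaks_rep2,
                               window = c(-5000, 1000)) {
  win <- promoterWindowRanges(ann, window)
  ov1 <- overlapsAny(win, peaks_rep1, ignore.strand = TRUE)
  ov2 <- overlapsAny(win, peaks_rep2, ignore.strand = TRUE)
  setNames(ov1 & ov2, mcols(ann)$gene_id)
}

#' Locate promoter methylation relative to the TSS
#'
#' Classifies each methylated promoter by where the replicate-consistent
#' peak overlap falls: only upstream (`up_only`, default -1/0 kb), only
#' downstream (`down_only`, 0/+1 kb), or both (`tss_both`); promoters with
#' neither are `none`.
#'
#' @inheritParams promoterMethylated
#' @param upWindow,downWindow the two TSS-relative windows.
#' @return named factor with levels `up_only`, `down_only`, `tss_both`,
#'   `none`.
#' @export
classifyMethylationLocation <- function(ann, peaks_rep1, peaks_rep2,
                                        upWindow = c(-1000, 0),
                                        downWindow = c(0, 1000)) {
  up <- promoterMethylated(ann, peaks_rep1, peaks_rep2, upWindow)
  down <- promoterMethylated(ann, peaks_rep1, peaks_rep2, downWindow)
  cat_ <- ifelse(up & down, "tss_both",
                 ifelse(up, "up_only", ifelse(down, "down_only", "none")))
  setNames(factor(cat_, levels = c("up_only", "down_only", "tss_both",
                                   "none")), mcols(ann)$gene_id)
}

#' Replicate-consistent promoter hypomethylation call
#'
#' A promoter is hypomethylated when every probe whose midpoint falls in
#' the TSS-relative window (default -1/0 kb) has a KS p-value of at least
#' `pFloor` in *both* replicates — i.e. every probe is confidently
#' non-enriched.  Windows holding fewer than `minProbesPresent` probes in
#' either replicate yield `no_call` rather than a vacuous `yes`.
#'
#' @param ann promoter annotation `GRanges`.
#' @param profile_rep1,profile_rep2 [KSProfile-class] objects for the two
#'   replicates.
#' @param window TSS-relative window `c(lo, hi)`.
#' @param pFloor minimum per-probe p-value (default 0.99).
#' @param minProbesPresent minimum probes required in the window
#'   (default 3).
#' @return named factor with levels `yes`, `no`, `no_call`.
#' @export
callHypomethylated <- function(ann, profile_rep1, profile_rep2,
                               window = c(-1000, 0), pFloor = 0.99,
                               minProbesPresent = 3L) {
  stat1 <- windowProbeStats(ann, profile_rep1, window)
  stat2 <- windowProbeStats(ann, profile_rep2, window)
  enough <- stat1$n >= minProbesPresent & stat2$n >= minProbesPresent
  all_high <- stat1$min_p >= pFloor & stat2$min_p >= pFloor
  out <- ifelse(!enough, "no_call", ifelse(all_high, "yes", "no"))
  setNames(factor(out, levels = c("yes", "no", "no_call")),
           mcols(ann)$gene_id)
}

# Per-gene count and minimum p of probes whose strand-aware TSS-relative
# midpoint lies in [lo, hi).
windowProbeStats <- function(ann, profile, window) {
  gr <- scoreRanges(profile)
  chr <- as.character(seqnames(gr))
  mid <- mcols(gr)$midpoint
  p <- mcols(gr)$p_value
  by_chr <- split(seq_along(gr), chr)
  n <- integer(length(ann)); minp <- rep(Inf, length(ann))
  tss <- mcols(ann)$tss
  gchr <- as.character(seqnames(ann))
  minus <- as.character(strand(ann)) == "-"
  for (g in seq_along(ann)) {
    idx <- by_chr[[gchr[g]]]
    if (is.null(idx)) next
    cm <- mid[idx]
    # rel in [lo, hi): + strand mid in [tss+lo, tss+hi);
    # - strand mid in (tss-hi, tss-lo]
    if (minus[g]) {
      lo <- tss[g] - window[2]; hi <- tss[g] - window[1]
      i1 <- findInterval(lo, cm) + 1L            # first mid > lo
      i2 <- findInterval(hi, cm)                 # last mid <= hi
    } else {
      lo <- tss[g] + window[1]; hi <- tss[g] + window[2]
      i1 <- findInterval(lo, cm, left.open = TRUE) + 1L  # first mid >= lo
      i2 <- findInterval(hi, cm, left.open = TRUE)       # last mid < hi
    }
    if (i2 >= i1) {
      sel <- idx[i1:i2]
      n[g] <- length(sel)
      minp[g] <- min(p[sel])
    }
  }
  list(n = n, min_p = minp)
}

#' Full per-promoter methylation call table for one stage
#'
#' Combines the replicate-consistent methylation call over the analysis
#' region, the TSS-relative location category, and the hypomethylation
#' call into one table.
#'
#' @inheritParams promoterMethylated
#' @inheritParams callHypomethylated
#' @param stage stage label recorded in the table.
#' @param region TSS-relative analysis region for the overall methylation
#'   call (default -5 kb/+1 kb).
#' @param upWindow,downWindow location windows (defaults -1/0 and 0/+1 kb).
#' @param hypoWindow hypomethylation window (default -1/0 kb).
#' @return `data.frame` with columns `gene_id`, `stage`, `methylated`,
#'   `category`, `hypomethylated`.
#' @export
callMethylationTable <- function(ann, peaks_rep1, peaks_rep2,
                                 profile_rep1, profile_rep2,
                                 stage = "unknown",
                                 region = c(-5000, 1000),
                                 upWindow = c(-1000, 0),
                                 downWindow = c(0, 1000),
                                 hypoWindow = c(-1000, 0),
                                 pFloor = 0.99, minProbesPresent = 3L) {
  meth <- promoterMethylated(ann, peaks_rep1, peaks_rep2, region)
  cat_ <- classifyMethylationLocation(ann, peaks_rep1, peaks_rep2,
                                      upWindow, downWindow)
  hypo <- callHypomethylated(ann, profile_rep1, profile_rep2, hypoWindow,
                             pFloor, minProbesPresent)
  data.frame(gene_id = mcols(ann)$gene_id, stage = stage,
             methylated = unname(meth), category = unname(cat_),
             hypomethylated = unname(hypo), stringsAsFactors = FALSE)
}
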