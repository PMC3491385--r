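#' Map probes into a TSS-relative window of one promoter
#'
#' Computes strand-aware TSS-relative probe positions
#' (`midpoint - tss` for `+` genes, `tss - midpoint` for `-` genes, so that
#' upstream is negative on both strands) and returns the probes whose
#' relative position falls in the half-open window `[lo, hi)`, ordered by
#' relative position.
#'
#' @param ps a [ProbeSet-class].
#' @param promoter a single-gene promoter annotation (one element of the
#'   `GRanges` returned by [promoterAnnotation()]).
#' @param window numeric `c(lo, hi)`, TSS-relative bp, `lo < hi`.
#' @return `data.frame` with columns `rel_pos` and `ratio` (possibly empty).
#' @export
mapProbesToPromoter <- function(ps, promoter, window = c(-1000, 0)) {
  stopifnot(is(ps, "ProbeSet"), length(promoter) == 1L,
            length(window) == 2L, window[1] < window[2])
  gr <- probeRanges(ps)
  same <- as.character(seqnames(gr)) == as.character(seqnames(promoter))
  mid <- probeMidpoints(ps)
  tss <- mcols(promoter)$tss
  rel <- if (as.character(strand(promoter)) == "-") tss - mid else mid - tss
  keep <- same & rel >= window[1] & rel < window[2]
  out <- data.frame(rel_pos = rel[keep], ratio = mcols(gr)$ratio[keep])
  out[order(out$rel_pos), , drop = FALSE]
}

#' MaxSixty promoter intensity summary
#'
#' The maximum, over all runs of `windowProbes` consecutive probes, of the
#' mean log2 ratio; the per-promoter methylation-intensity summary used for
#' replicate and stage scatter comparisons.  When a region holds fewer than
#' `windowProbes` probes the plain mean of all of them is returned.
#'
#' @param values ordered probe ratios for one promoter region.
#' @param windowProbes run length (default 60).
#' @return a single numeric summary.
#' @examples
#' maxSixty(rep(0.5, 100))       # 0.5
#' maxSixty(1:10)                # fewer than 60 probes: mean(1:10)
#' @export
maxSixty <- function(values, windowProbes = 60L) {
  n <- length(values)
  if (n == 0L) stop("maxSixty needs at least one probe value")
  if (n < windowProbes) return(mean(values))
  cs <- cumsum(c(0, values))
  max((cs[(windowProbes + 1):(n + 1)] - cs[1:(n - windowProbes + 1)]) /
        windowProbes)
}

#' Pearson correlation of per-promoter summaries between replicates
#'
#' @param a,b numeric vectors of per-promoter summaries (e.g. [maxSixty()]
#'   values).  If both are named they are aligned by name; otherwise they
#'   must be in matching gene order.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when either
#'   vector has zero variance.
#' @export
replicateCorrelation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("replicate summaries cover different gene sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("replicate summaries must have equal length")
  }
  if (length(a) < 3L) stop("need at least 3 promoters to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a replicate summary; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
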