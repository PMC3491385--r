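#' ProbeSet: tiling-array probes for one replicate of one sample
#'
#' A `ProbeSet` holds the probes of a single MeDIP-chip replicate: genomic
#' intervals plus the log2 MeDIP/input ratio measured on each probe.  Probes
#' are kept sorted by (chromosome, start) and must be unique within a
#' replicate.
#'
#' @slot probes `GRanges` with a numeric metadata column `ratio`
#'   (log2 MeDIP/input, dimensionless).  Ranges are 1-based closed as usual
#'   for `GRanges`; the text readers/writers convert from/to 0-based
#'   half-open coordinates.
#' @slot replicate single string identifying the replicate (e.g. `"rep1"`).
#' @slot stage single string with the sample label (e.g. `"pre_mbt"`,
#'   `"mbt"`, `"post_mbt"`, `"sperm"`); treated as an opaque label.
#'
#' @seealso [ProbeSet()], [readProbeTable()], [normalizeCenter()]
#' @export
setClass("ProbeSet",
  representation(probes = "GRanges", replicate = "character",
                 stage = "character"))

setValidity("ProbeSet", function(object) {
  gr <- object@probes
  msg <- character()
  if (!("ratio" %in% colnames(mcols(gr))))
    msg <- c(msg, "probes must carry a 'ratio' metadata column")
  else if (!is.numeric(mcols(gr)$ratio) || any(!is.finite(mcols(gr)$ratio)))
    msg <- c(msg, "all probe ratios must be finite numbers")
  if (length(object@replicate) != 1L || length(object@stage) != 1L)
    msg <- c(msg, "replicate and stage must be single strings")
  if (length(gr) > 1L) {
    o <- order(as.character(seqnames(gr)), start(gr), end(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "probes must be sorted by (chrom, start, end)")
    key <- paste(as.character(seqnames(gr)), start(gr), end(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate probes (same chrom/start/end) in one replicate")
  }
  if (length(msg)) msg else TRUE
})

#' KSProfile: per-probe windowed KS enrichment scores
#'
#' One record per probe of a [ProbeSet], carrying the one-sided KS statistic
#' and p-value of the 750-bp (by default) window centred on that probe,
#' tested against the array background.
#'
#' @slot scores `GRanges` mirroring the probe ranges, with metadata columns
#'   `midpoint` (0-based genomic midpoint), `ratio`, `d_statistic` in
#'   `[0, 1]`, `p_value` in `(0, 1]`, `n_window` (probes in the scoring
#'   window) and `no_score` (`TRUE` when the window held fewer than the
#'   minimum number of probes, in which case `p_value` is 1).
#' @slot windowBp width in bp of the scoring window.
#' @slot background background definition used
#'   (`"exclude_window"`, `"full_array"` or `"chromosome"`).
#' @slot params list with replicate/stage labels and scoring options.
#'
#' @seealso [ksProbeScores()], [callPeaks()]
#' @export
setClass("KSProfile",
  representation(scores = "GRanges", windowBp = "numeric",
                 background = "character", params = "list"))

setValidity("KSProfile", function(object) {
  m <- mcols(object@scores)
  need <- c("midpoint", "d_statistic", "p_value", "n_window", "no_score")
  if (!all(need %in% colnames(m)))
    return(paste("scores must carry columns:", paste(need, collapse = ", ")))
  p <- m$p_value; d <- m$d_statistic
  if (any(p <= 0 | p > 1)) return("p_value must lie in (0, 1]")
  if (any(d < 0 | d > 1)) return("d_statistic must lie in [0, 1]")
  TRUE
})
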