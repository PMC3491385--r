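#' Observed/expected CpG ratio of a DNA sequence
#'
#' `(N_CpG * L) / (N_C * N_G)`, the CpG-island hallmark statistic, where
#' `N_CpG` counts overlapping `CG` dinucleotides.  `N` bases are excluded
#' from all counts and from the effective length `L`.  Returns 0 when the
#' sequence contains no C or no G.
#'
#' @param seq a single DNA string (A/C/G/T/N, case-insensitive).
#' @return the o/e CG ratio (non-negative; 2.0 for pure `CG` repeats).
#' @examples
#' oeCgRatio("CGCGCGCGCG")  # 2
#' oeCgRatio("ACGT")        # 4
#' oeCgRatio("ATATAT")      # 0
#' @export
oeCgRatio <- function(seq) {
  x <- prepSeq(seq)
  if (x$len < 2L) stop("sequence must have length >= 2")
  L <- x$len - x$nN
  nC <- x$nC; nG <- x$nG
  if (nC == 0 || nG == 0 || L == 0) return(0)
  x$nCG * L / (nC * nG)
}

#' CG content of a DNA sequence
#'
#' `(N_C + N_G) / L` with `N` bases excluded from the counts and from `L`.
#'
#' @inheritParams oeCgRatio
#' @return fraction in `[0, 1]`.
#' @examples
#' cgContent("CGCG")  # 1
#' cgContent("ACGT")  # 0.5
#' @export
cgContent <- function(seq) {
  x <- prepSeq(seq)
  if (x$len < 1L) stop("sequence must be non-empty")
  L <- x$len - x$nN
  if (L == 0) return(0)
  (x$nC + x$nG) / L
}

# Character -> indicator vectors + totals; shared by the scanning code.
prepSeq <- function(seq) {
  if (is(seq, "XString") || is(seq, "XStringSet")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(ch) && !all(ch %in% c("A", "C", "G", "T", "N")))
    stop("sequence alphabet restricted to A/C/G/T/N")
  isC <- ch == "C"; isG <- ch == "G"; isN <- ch == "N"
  n <- length(ch)
  isCG <- if (n >= 2L) isC[-n] & isG[-1L] else logical(0)
  list(ch = ch, len = n, isC = isC, isG = isG, isN = isN, isCG = isCG,
       nC = sum(isC), nG = sum(isG), nN = sum(isN), nCG = sum(isCG))
}

# Window statistics at every requested offset via cumulative sums.
# Offsets are 0-based; dinucleotides are counted when both bases fall
# inside the window.
windowScan <- function(x, windowBp, offsets) {
  csC <- cumsum(c(0L, x$isC)); csG <- cumsum(c(0L, x$isG))
  csN <- cumsum(c(0L, x$isN)); csCG <- cumsum(c(0L, x$isCG, 0L))
  i <- offsets + 1L; j <- offsets + windowBp
  nC <- csC[j + 1L] - csC[i]
  nG <- csG[j + 1L] - csG[i]
  nN <- csN[j + 1L] - csN[i]
  nCG <- csCG[j] - csCG[i]          # dinuc start positions i .. j-1
  L <- windowBp - nN
  oe <- ifelse(nC > 0 & nG > 0 & L > 0, nCG * L / (nC * nG), 0)
  cg <- ifelse(L > 0, (nC + nG) / L, 0)
  data.frame(offset = offsets, oe_ratio = oe, cg_content = cg,
             n_fraction = nN / windowBp)
}

scanOffsets <- function(L, windowBp, stepBp) {
  offs <- seq.int(0L, L - windowBp, by = stepBp)
  last <- L - windowBp
  if (offs[length(offs)] != last) offs <- c(offs, last)
  offs
}

#' Classify a promoter as high- or low-CpG (HCP/LCP)
#'
#' Scans the promoter sequence (canonically the 1-kb region upstream of the
#' TSS, 5'->3' on the gene's strand) with a sliding window and scores the
#' promoter HCP when any full window reaches both thresholds:
#' o/e CG ratio `>= oeMin` and CG content strictly `> cgMin` (set
#' `cgStrict = FALSE` for an inclusive content threshold).  Promoters with
#' no qualifying window are LCPs; the zebrafish-adapted thresholds are
#' 0.65 / 0.30 over a 500-bp window.
#'
#' @inheritParams oeCgRatio
#' @param windowBp sliding-window width (default 500).
#' @param stepBp scan step (default 1, the exhaustive scan; the final
#'   offset `L - windowBp` is always included).
#' @param oeMin minimum o/e CG ratio (inclusive).
#' @param cgMin CG content threshold (strict by default).
#' @param cgStrict whether the content comparison is strict (`>`).
#' @return one-row `data.frame`: `class` (`"HCP"`/`"LCP"`), `best_offset`,
#'   `best_oe`, `best_cg` of the maximal-o/e window (ties to the smallest
#'   offset; among qualifying windows when any), `short_seq` (sequence
#'   shorter than the window: forced LCP), `high_n` (some window has more
#'   than 10% `N`).
#' @export
classifyPromoter <- function(seq, windowBp = 500L, stepBp = 1L,
                             oeMin = 0.65, cgMin = 0.30, cgStrict = TRUE) {
  x <- prepSeq(seq)
  if (x$len < windowBp)
    return(data.frame(class = "LCP", best_offset = NA_integer_,
                      best_oe = NA_real_, best_cg = NA_real_,
                      short_seq = TRUE, high_n = NA))
  sc <- windowScan(x, windowBp, scanOffsets(x$len, windowBp, stepBp))
  pass_cg <- if (cgStrict) sc$cg_content > cgMin else sc$cg_content >= cgMin
  qual <- sc$oe_ratio >= oeMin & pass_cg
  pool <- if (any(qual)) sc[qual, ] else sc
  best <- pool[which.max(pool$oe_ratio), ]  # which.max: first maximum
  data.frame(class = if (any(qual)) "HCP" else "LCP",
             best_offset = best$offset, best_oe = best$oe_ratio,
             best_cg = best$cg_content, short_seq = FALSE,
             high_n = any(sc$n_fraction > 0.10))
}

#' Classify many promoter sequences
#'
#' Vectorized wrapper around [classifyPromoter()].
#'
#' @param seqs named character vector or `DNAStringSet`
#'   (names = gene ids).
#' @inheritParams classifyPromoter
#' @return `data.frame` with `gene_id` plus the [classifyPromoter()]
#'   columns, one row per sequence.
#' @export
classifyPromoters <- function(seqs, windowBp = 500L, stepBp = 1L,
                              oeMin = 0.65, cgMin = 0.30, cgStrict = TRUE) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  rows <- lapply(seqs, classifyPromoter, windowBp = windowBp,
                 stepBp = stepBp, oeMin = oeMin, cgMin = cgMin,
                 cgStrict = cgStrict)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), out)
}

#' CG density profile along a sequence
#'
#' Per-offset CG content and o/e CG ratio of a sliding window, the series
#' used for CG-density plots (500-bp window moving in 10-bp steps by
#' convention).
#'
#' @inheritParams classifyPromoter
#' @return `data.frame` with `offset`, `oe_ratio`, `cg_content`,
#'   `n_fraction`.
#' @export
cgDensityProfile <- function(seq, windowBp = 500L, stepBp = 10L) {
  x <- prepSeq(seq)
  if (x$len < windowBp) stop("sequence shorter than the window")
  windowScan(x, windowBp, scanOffsets(x$len, windowBp, stepBp))
}

#' Count CpG islands and flag CGI clusters in a region
#'
#' Qualifying windows (same thresholds as [classifyPromoter()]) are merged
#' when they overlap or touch, each merged run forming one CpG island
#' (CGI).  Regions with three or more islands are flagged as CGI clusters,
#' the configuration characteristic of developmental regulator loci.
#'
#' @inheritParams classifyPromoter
#' @param stepBp scan step (default 10).
#' @return list with `n_cgi`, `is_cluster` (`n_cgi >= 3`) and an
#'   `islands` data.frame of merged 0-based half-open intervals.
#' @export
countCgiAndClusters <- function(seq, windowBp = 500L, stepBp = 10L,
                                oeMin = 0.65, cgMin = 0.30,
                                cgStrict = TRUE) {
  x <- prepSeq(seq)
  if (x$len < windowBp) stop("region shorter than the window")
  sc <- windowScan(x, windowBp, scanOffsets(x$len, windowBp, stepBp))
  pass_cg <- if (cgStrict) sc$cg_content > cgMin else sc$cg_content >= cgMin
  qual <- which(sc$oe_ratio >= oeMin & pass_cg)
  if (!length(qual))
    return(list(n_cgi = 0L, is_cluster = FALSE,
                islands = data.frame(start = integer(), end = integer())))
  s <- sc$offset[qual]; e <- sc$offset[qual] + windowBp
  keep_start <- c(TRUE, s[-1] > e[-length(e)])   # gap > 0 starts new island
  isl_id <- cumsum(keep_start)
  islands <- data.frame(start = tapply(s, isl_id, min),
                        end = tapply(e, isl_id, max), row.names = NULL)
  list(n_cgi = nrow(islands), is_cluster = nrow(islands) >= 3L,
       islands = islands)
}

#' Read promoter sequences from FASTA
#'
#' One record per promoter; the record id (text before the first space) is
#' the gene id.
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
readPromoterSequences <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
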