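# Shared fixture builders and independent oracles used across test files.

# Regularly spaced probes on one chromosome with given ratios.
gridProbeSet <- function(ratios, chrom = "chr1", start0 = 0, spacing = 100,
                         plen = 50, replicate = "rep1", stage = "test") {
  n <- length(ratios)
  s <- start0 + (seq_len(n) - 1L) * spacing
  ProbeSet(rep(chrom, n), s, s + plen, ratios, replicate, stage)
}

# Brute-force D+ = sup_x [F_bg(x) - F_win(x)] evaluated on a fine grid of
# candidate points (all pooled values and points just below them).
bruteDplus <- function(w, bg) {
  xs <- sort(unique(c(w, bg)))
  cand <- sort(c(xs, xs - 1e-9))
  max(0, max(vapply(cand, function(x)
    mean(bg <= x) - mean(w <= x), numeric(1))))
}

# Exhaustive null distribution of D+ for tiny m + n: every labelling of
# the pooled ranks.
bruteExactP <- function(d, m, n) {
  combos <- utils::combn(m + n, m)
  vals <- apply(combos, 2, function(ix) {
    pool <- seq_len(m + n)
    bruteDplus(pool[ix], pool[-ix])
  })
  mean(vals >= d - 1e-12)
}

# Brute-force run scanner for peak calling on a scored profile.
brutePeaks <- function(chrom, mid, p, start0, end0, cutoff = 0.01,
                       minProbes = 2L, maxGap = 1000) {
  out <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) >= minProbes)
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom[run[1]], start = start0[run[1]],
        end = end0[run[length(run)]], n_probes = length(run),
        min_p = min(p[run]))
  }
  for (i in seq_along(p)) {
    ok <- p[i] <= cutoff
    joins <- length(run) > 0 && ok &&
      chrom[i] == chrom[run[length(run)]] &&
      (mid[i] - mid[run[length(run)]]) <= maxGap
    if (joins) {
      run <- c(run, i)
    } else {
      flush(run)
      run <- if (ok) i else integer(0)
    }
  }
  flush(run)
  if (!length(out)) return(data.frame(chrom = character(),
                                      start = numeric(), end = numeric(),
                                      n_probes = integer(),
                                      min_p = numeric()))
  do.call(rbind, out)
}

peaksAsDf <- function(pk) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
             start = GenomicRanges::start(pk) - 1L,
             end = GenomicRanges::end(pk),
             n_probes = S4Vectors::mcols(pk)$n_probes,
             min_p = S4Vectors::mcols(pk)$min_p)
}

# Independent per-window sequence statistics via string substitution
# counting (gsub removal), used as the enumeration oracle for the
# classifier: CG 2-mers never overlap, so gsub counts them exactly.
oracleWindowStats <- function(seq, off, w) {
  win <- substr(seq, off + 1L, off + w)
  cnt <- function(pat) {
    (nchar(win) - nchar(gsub(pat, "", win, fixed = TRUE))) / nchar(pat)
  }
  nC <- cnt("C"); nG <- cnt("G"); nN <- cnt("N"); nCG <- cnt("CG")
  L <- w - nN
  list(oe = if (nC > 0 && nG > 0 && L > 0) nCG * L / (nC * nG) else 0,
       cg = if (L > 0) (nC + nG) / L else 0)
}

oracleClassify <- function(seq, w = 500L, oeMin = 0.65, cgMin = 0.30) {
  L <- nchar(seq)
  if (L < w) return("LCP")
  for (off in 0:(L - w)) {
    st <- oracleWindowStats(seq, off, w)
    if (st$oe >= oeMin && st$cg > cgMin) return("HCP")
  }
  "LCP"
}

# Two-sided Fisher p by direct hypergeometric enumeration
# (probability-mass extremity criterion).
oracleFisherP <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

randomSequence <- function(len, probs = c(A = 0.3, C = 0.2, G = 0.2,
                                          T = 0.3)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

revComp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
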