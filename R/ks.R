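#' One-sided two-sample Kolmogorov-Smirnov test (window vs background)
#'
#' Tests whether the window values are stochastically larger than the
#' background (the direction of MeDIP enrichment, which raises log2
#' ratios).  The statistic is
#' `D+ = sup_x [ECDF_bg(x) - ECDF_window(x)]`, clamped to `[0, 1]`.
#'
#' Three p-value methods are available.  `"exact"` computes the exact null
#' probability `P(D+ >= d)` by a lattice-path recursion (assumes continuous
#' data; with ties it is conditional on the observed pattern).
#' `"asymptotic"` uses `exp(-2 d^2 m n / (m + n))`, clamped to `(0, 1]` —
#' the classical large-sample bound, deliberately conservative near
#' `d = 0`, and the formula applied in array-scale probe scoring.
#' `"permutation"` is a label-shuffle Monte-Carlo oracle.  The default
#' `"auto"` follows the `stats::ks.test()` convention: exact when
#' `m * n <= 10000`, asymptotic otherwise.
#'
#' @param window_values numeric, non-empty window sample (size `m`).
#' @param background_values numeric background sample (size `n`).
#' @param method `"auto"`, `"exact"`, `"asymptotic"` or `"permutation"`.
#' @param nPermutations shuffles for `method = "permutation"`.
#' @return list with `d` (the clamped `D+`), `p` and `method` used.
#' @examples
#' oneSidedKS(c(5, 6, 7), rnorm(50))     # clearly enriched window
#' @export
oneSidedKS <- function(window_values, background_values,
                       method = c("auto", "exact", "asymptotic",
                                  "permutation"),
                       nPermutations = 10000L) {
  method <- match.arg(method)
  m <- length(window_values); n <- length(background_values)
  if (m == 0L) stop("window sample is empty")
  if (n == 0L) stop("background sample is empty")
  d <- ksDplus(window_values, background_values)
  if (method == "auto")
    method <- if (m * n <= 10000) "exact" else "asymptotic"
  p <- switch(method,
    asymptotic = ksAsymptoticP(d, m, n),
    exact = ksExactP(d, m, n),
    permutation = ksPermutationP(window_values, background_values, d,
                                 nPermutations))
  list(d = d, p = p, method = method)
}

# D+ = sup_x [F_bg(x) - F_win(x)], evaluated just below each window value
# (the sup of the step function is attained there); ties handled through
# strictly-less counts.
ksDplus <- function(w, bg) {
  sw <- sort(w); m <- length(w); n <- length(bg)
  nb <- findInterval(sw, sort(bg), left.open = TRUE)  # bg strictly below
  nw <- findInterval(sw, sw, left.open = TRUE)        # window strictly below
  min(1, max(0, max(nb / n - nw / m)))
}

ksAsymptoticP <- function(d, m, n) {
  min(1, exp(-2 * d^2 * m * n / (m + n)))
}

# Exact P(D+ >= d): count monotone lattice paths from (0,0) to (m,n)
# (i window values, j background values consumed) whose every node keeps
# j/n - i/m < d; the complement over all C(m+n, m) orderings is the
# rejection probability.  O(m n) time, numerically safe in doubles for the
# m*n <= 10000 sizes this is used at.
ksExactP <- function(d, m, n) {
  if (d <= 0) return(1)
  if (d > 1) d <- 1
  # dp[i+1] = number of allowed paths reaching (i, j) for current j
  dp <- numeric(m + 1)
  allowed0 <- function(i, j) (j / n - i / m) < d - 1e-12
  dp[1] <- 1  # node (0,0): 0 < d holds since d > 0
  for (i in 1:m) dp[i + 1] <- dp[i]  # j = 0 row: -i/m < d always
  for (j in 1:n) {
    dp[1] <- if (allowed0(0, j)) dp[1] else 0
    for (i in 1:m) {
      dp[i + 1] <- if (allowed0(i, j)) dp[i + 1] + dp[i] else 0
    }
  }
  total <- choose(m + n, m)
  p <- 1 - dp[m + 1] / total
  min(1, max(p, .Machine$double.xmin))
}

# Monte-Carlo permutation p: reassign window labels within the pooled
# sample, rank-based fast path when the pooled values are tie-free.
ksPermutationP <- function(w, bg, d_obs, B = 10000L) {
  m <- length(w); n <- length(bg)
  pool <- c(w, bg)
  hits <- 0L
  if (!anyDuplicated(pool)) {
    for (b in seq_len(B)) {
      s <- sort.int(sample.int(m + n, m))
      # with distinct pooled values, #bg below the j-th window value = s_j - j
      db <- max(0, max((s - seq_len(m)) / n - (seq_len(m) - 1) / m))
      if (db >= d_obs - 1e-12) hits <- hits + 1L
    }
  } else {
    for (b in seq_len(B)) {
      idx <- sample.int(m + n, m)
      if (ksDplus(pool[idx], pool[-idx]) >= d_obs - 1e-12) hits <- hits + 1L
    }
  }
  max(hits, 1L) / B  # keep p in (0, 1]
}

#' Windowed KS enrichment scores for every probe
#'
#' For each probe, the window sample is the set of ratios of all probes
#' (same chromosome) whose midpoint lies within `windowBp / 2` of the probe
#' midpoint, and the background is the rest of the array (by default).  The
#' per-probe score is the one-sided asymptotic KS p-value of that window —
#' low p means locally elevated ratios, i.e. likely methylation; p near 1
#' means the window looks confidently non-enriched.  Probes whose window
#' holds fewer than `minWindowProbes` probes are flagged and given
#' `p_value = 1`.
#'
#' The p-value is the asymptotic `exp(-2 d^2 m n / (m + n))`: at array
#' scale the exact recursion is unaffordable, and the formula's
#' conservatism near `d = 0` (p driven to 1 for any unremarkable window)
#' is what gives the hypomethylation rule (`all probes p >= pFloor`, see
#' [callHypomethylated()]) its operating range.
#'
#' @param ps a [ProbeSet-class]; expected to be centered
#'   (see [normalizeCenter()]) — a warning is emitted otherwise.  The KS
#'   score itself is rank-based and unaffected by centering.
#' @param windowBp scoring window width in bp (default 750).
#' @param minWindowProbes minimum probes for a scored window (default 4).
#' @param background `"exclude_window"` (default: all probes off the
#'   window), `"full_array"`, or `"chromosome"` (probes of the same
#'   chromosome, excluding the window).
#' @return a [KSProfile-class] with one record per probe.
#' @export
ksProbeScores <- function(ps, windowBp = 750,
                          minWindowProbes = 4L,
                          background = c("exclude_window", "full_array",
                                         "chromosome")) {
  stopifnot(is(ps, "ProbeSet"))
  background <- match.arg(background)
  if (length(ps) == 0L) stop("empty ProbeSet")
  r_all <- probeRatios(ps)
  if (abs(median(r_all)) > 0.05)
    warning("ProbeSet does not look centered (median ratio != 0); ",
            "KS scores are rank-based and unaffected, but peak summaries ",
            "assume centered ratios")
  mid <- probeMidpoints(ps)
  chr <- as.character(seqnames(probeRanges(ps)))
  half <- windowBp / 2
  N_tot <- length(r_all)
  sorted_all <- sort(r_all)

  d_out <- numeric(N_tot); p_out <- rep(1, N_tot)
  m_out <- integer(N_tot); flag <- logical(N_tot)

  for (cn in unique(chr)) {
    sel <- which(chr == cn)
    cm <- mid[sel]; cr <- r_all[sel]
    nc <- length(sel)
    # window index bounds per probe (midpoints sorted within chromosome)
    ws <- findInterval(cm - half, cm, left.open = TRUE) + 1L
    we <- findInterval(cm + half, cm)
    mwin <- we - ws + 1L
    m_out[sel] <- mwin
    sorted_bgpool <- if (background == "chromosome") sort(cr) else sorted_all
    n_pool <- length(sorted_bgpool)
    for (mv in unique(mwin)) {
      rows <- which(mwin == mv)
      if (mv < minWindowProbes) { flag[sel[rows]] <- TRUE; next }
      # gather window ratios into an (nrow x mv) matrix
      idx <- outer(ws[rows], 0:(mv - 1L), "+")
      W <- matrix(cr[idx], nrow = length(rows))
      cnt_pool <- matrix(findInterval(W, sorted_bgpool, left.open = TRUE),
                         nrow = length(rows))
      cnt_win <- matrix(0L, nrow = length(rows), ncol = mv)
      for (jj in seq_len(mv)) {
        acc <- integer(length(rows))
        for (kk in seq_len(mv)) if (kk != jj)
          acc <- acc + (W[, kk] < W[, jj])
        cnt_win[, jj] <- acc
      }
      if (background == "full_array") {
        n_bg <- n_pool
        Fbg <- cnt_pool / n_bg
      } else {
        n_bg <- n_pool - mv
        Fbg <- (cnt_pool - cnt_win) / n_bg
      }
      dmat <- Fbg - cnt_win / mv
      dvec <- pmin(1, pmax(0, dmat[cbind(seq_len(nrow(dmat)),
                                         max.col(dmat, "first"))]))
      d_out[sel[rows]] <- dvec
      p_out[sel[rows]] <- pmin(1, exp(-2 * dvec^2 * mv * n_bg / (mv + n_bg)))
    }
  }

  gr <- probeRanges(ps)
  mcols(gr) <- DataFrame(midpoint = mid, ratio = r_all, d_statistic = d_out,
                         p_value = p_out, n_window = m_out, no_score = flag)
  new("KSProfile", scores = gr, windowBp = windowBp, background = background,
      params = list(replicate = replicateId(ps), stage = stageLabel(ps),
                    minWindowProbes = minWindowProbes))
}

#' Accessors for KSProfile objects
#'
#' `scoreRanges()` returns the per-probe `GRanges` with score columns;
#' `pValues()` the p-value vector.
#'
#' @param x a [KSProfile-class].
#' @name KSProfile-accessors
#' @aliases scoreRanges pValues
NULL

#' @rdname KSProfile-accessors
#' @export
setMethod("scoreRanges", "KSProfile", function(x) x@scores)

#' @rdname KSProfile-accessors
#' @export
setMethod("pValues", "KSProfile", function(x) mcols(x@scores)$p_value)

#' @export
setMethod("length", "KSProfile", function(x) length(x@scores))

setMethod("show", "KSProfile", function(object) {
  p <- pValues(object)
  cat(sprintf(
    "KSProfile: %d probes | window %g bp | background %s\n  p <= 0.01: %d probes (%.2f%%) | unscored: %d\n",
    length(p), object@windowBp, object@background, sum(p <= 0.01),
    100 * mean(p <= 0.01), sum(mcols(object@scores)$no_score)))
})

#' Write a KSProfile as TSV
#'
#' Columns: `chrom`, `midpoint` (0-based), `d`, `p`, `n_window`.
#'
#' @param profile a [KSProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKSProfile <- function(profile, path) {
  gr <- scoreRanges(profile)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   midpoint = mcols(gr)$midpoint, d = mcols(gr)$d_statistic,
                   p = mcols(gr)$p_value, n_window = mcols(gr)$n_window)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
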