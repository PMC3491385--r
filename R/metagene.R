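#' TSS-anchored metagene profile of methylation enrichment
#'
#' Averages replicate-mean probe ratios in TSS-relative bins over a gene
#' set.  By default the gene set is restricted to genes with high
#' enrichment probability: at least one probe with KS `p <= pCutoff`
#' within the profiled range, in both replicates.
#'
#' Both replicates must tile identical probe coordinates (they do on the
#' same array design); their ratios are averaged probe-wise before
#' binning.
#'
#' @param ann promoter annotation `GRanges`.
#' @param ps_rep1,ps_rep2 [ProbeSet-class] replicates of one stage.
#' @param profile_rep1,profile_rep2 optional [KSProfile-class] objects used
#'   for the qualifying rule; both or neither.
#' @param range TSS-relative profiled window `c(lo, hi)`; `binBp` must
#'   divide its length.
#' @param binBp bin width in bp (default 100, the probe-spacing scale).
#' @param pCutoff qualifying probe p cutoff (default 0.01).
#' @param genes optional character vector restricting the gene set before
#'   the qualifying rule is applied.
#' @return `data.frame` with `bin_lo`, `bin_hi`, `mean_ratio`, `n_probes`;
#'   bins with no probes have `NA` mean.  The qualifying gene count is in
#'   attribute `n_genes`.
#' @export
metageneProfile <- function(ann, ps_rep1, ps_rep2,
                            profile_rep1 = NULL, profile_rep2 = NULL,
                            range = c(-2000, 2000), binBp = 100,
                            pCutoff = 0.01, genes = NULL) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  width <- range[2] - range[1]
  if (width %% binBp != 0) stop("binBp must divide the range length")
  if (!is.null(genes)) {
    ann <- ann[mcols(ann)$gene_id %in% genes]
  }
  if (length(ann) == 0L) stop("empty gene set")
  if (xor(is.null(profile_rep1), is.null(profile_rep2)))
    stop("provide both replicate profiles or neither")
  if (!is.null(profile_rep1)) {
    q1 <- genesWithEnrichedProbe(ann, profile_rep1, range, pCutoff)
    q2 <- genesWithEnrichedProbe(ann, profile_rep2, range, pCutoff)
    ann <- ann[q1 & q2]
    if (length(ann) == 0L)
      stop("no gene qualifies (no probe with p <= pCutoff in both replicates)")
  }
  avg <- averagedRatios(ps_rep1, ps_rep2)
  nb <- width %/% binBp
  sums <- numeric(nb); counts <- integer(nb)
  for (g in seq_along(ann)) {
    mp <- mapProbesToPromoter(avg, ann[g], range)
    if (!nrow(mp)) next
    b <- floor((mp$rel_pos - range[1]) / binBp) + 1L
    tab_s <- tapply(mp$ratio, b, sum)
    idx <- as.integer(names(tab_s))
    sums[idx] <- sums[idx] + as.numeric(tab_s)
    counts[idx] <- counts[idx] + as.integer(table(b))
  }
  out <- data.frame(bin_lo = range[1] + (seq_len(nb) - 1L) * binBp,
                    bin_hi = range[1] + seq_len(nb) * binBp,
                    mean_ratio = ifelse(counts > 0, sums / counts, NA_real_),
                    n_probes = counts)
  attr(out, "n_genes") <- length(ann)
  out
}

# TRUE per gene when >= 1 probe in the TSS-relative range has p <= cutoff.
genesWithEnrichedProbe <- function(ann, profile, range, pCutoff) {
  gr <- scoreRanges(profile)
  enriched <- gr[mcols(gr)$p_value <= pCutoff]
  if (length(enriched) == 0L) return(rep(FALSE, length(ann)))
  win <- promoterWindowRanges(ann, range)
  epts <- GRanges(seqnames(enriched),
                  IRanges(start = floor(mcols(enriched)$midpoint) + 1L,
                          width = 1L))
  overlapsAny(win, epts, ignore.strand = TRUE)
}

# Probe-wise replicate average as a new ProbeSet (requires identical
# coordinates in both replicates).
averagedRatios <- function(ps1, ps2) {
  g1 <- probeRanges(ps1); g2 <- probeRanges(ps2)
  if (length(g1) != length(g2) ||
      !all(as.character(seqnames(g1)) == as.character(seqnames(g2))) ||
      !all(start(g1) == start(g2)) || !all(end(g1) == end(g2)))
    stop("replicates must tile identical probe coordinates")
  ProbeSet(as.character(seqnames(g1)), start(g1) - 1L, end(g1),
           (mcols(g1)$ratio + mcols(g2)$ratio) / 2,
           replicate = "rep_mean", stage = stageLabel(ps1))
}

#' Median promoter methylation level over a gene set
#'
#' Per gene, the mean replicate-averaged log2 ratio of probes in the
#' TSS-relative window; the reported level is the median over genes (genes
#' with no probe in the window are dropped).
#'
#' @inheritParams metageneProfile
#' @param window TSS-relative window `c(lo, hi)` (default -1/0 kb).
#' @return single numeric median level.
#' @export
medianMethylationLevel <- function(ann, ps_rep1, ps_rep2,
                                   window = c(-1000, 0), genes = NULL) {
  if (!is.null(genes)) ann <- ann[mcols(ann)$gene_id %in% genes]
  if (length(ann) == 0L) stop("empty gene set")
  avg <- averagedRatios(ps_rep1, ps_rep2)
  means <- vapply(seq_along(ann), function(g) {
    mp <- mapProbesToPromoter(avg, ann[g], window)
    if (nrow(mp)) mean(mp$ratio) else NA_real_
  }, numeric(1))
  median(means, na.rm = TRUE)
}

#' Stage-to-stage maintenance of methylation calls
#'
#' Set algebra between consecutive stages: for each pair, the genes whose
#' state is maintained, gained or lost, plus per-stage counts and the
#' percent increase between consecutive stages.
#'
#' @param callsByStage named list of call tables from
#'   [callMethylationTable()] (or any data.frame with `gene_id` and the
#'   chosen state column), one per stage, identical gene universes.
#' @param stages stage order; defaults to `names(callsByStage)`.
#' @param state `"methylated"` (logical column) or `"hypomethylated"`
#'   (the `yes` level of the tri-state call).
#' @return list with `sets` (character vectors per stage), `counts`,
#'   `transitions` (data.frame per consecutive pair with maintained /
#'   gained / lost counts and percent increase), and the per-pair gene
#'   sets in `transition_sets`.
#' @export
stageTransitions <- function(callsByStage, stages = names(callsByStage),
                             state = c("methylated", "hypomethylated")) {
  state <- match.arg(state)
  stopifnot(length(stages) >= 2L, all(stages %in% names(callsByStage)))
  universe <- sort(callsByStage[[stages[1]]]$gene_id)
  sets <- lapply(stages, function(s) {
    tab <- callsByStage[[s]]
    if (!identical(sort(tab$gene_id), universe))
      stop("gene universes differ between stages")
    if (state == "methylated") tab$gene_id[tab$methylated]
    else tab$gene_id[tab$hypomethylated == "yes"]
  })
  names(sets) <- stages
  trans <- list(); rows <- list()
  for (k in seq_len(length(stages) - 1L)) {
    a <- sets[[k]]; b <- sets[[k + 1L]]
    maintained <- intersect(a, b)
    gained <- setdiff(b, a)
    lost <- setdiff(a, b)
    pair <- paste(stages[k], stages[k + 1L], sep = "->")
    trans[[pair]] <- list(maintained = maintained, gained = gained,
                          lost = lost)
    rows[[pair]] <- data.frame(
      from = stages[k], to = stages[k + 1L], n_from = length(a),
      n_to = length(b), maintained = length(maintained),
      gained = length(gained), lost = length(lost),
      percent_increase = if (length(a)) 100 * (length(b) - length(a)) /
        length(a) else NA_real_)
  }
  list(sets = sets, counts = setNames(lengths(sets), stages),
       transitions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       transition_sets = trans)
}
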