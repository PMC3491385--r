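#' Configuration for the synthetic MeDIP tiling experiment
#'
#' Defines the simulated study conditions: array geometry (probes tiling
#' -15 kb to +5 kb around each TSS, the design of the promoter arrays this
#' package targets), the planted methylation truth, the noise model, and
#' the cohort/mark association structure.  All randomness downstream is a
#' pure function of `seed`.
#'
#' The truth model plants, per gene and stage, one of three states:
#' *methylated* (a positive log2-ratio domain of depth `effectSize` near
#' the TSS, located upstream-only, downstream-only or astride the TSS),
#' *hypomethylated* (a negative domain of depth `hypoEffect` spanning
#' `hypoDomain`, emulating the confidently sub-genome-average CG-rich
#' domains seen around maintained-hypomethylated promoters), or
#' *genome-average* (no domain).  Methylated sets are nested across stages
#' (methylation, once gained, is maintained), matching the observed
#' stage-to-stage stability; the hypomethylated set is constant across
#' stages.  Probe ratios add shared and replicate-specific Gaussian noise:
#' `sqrt(rho) * sigma` of the noise is common to both replicates.
#'
#' @param nGenes number of simulated genes.
#' @param tileRange TSS-relative tiled range `c(lo, hi)` in bp
#'   (default `c(-15000, 5000)`).
#' @param probeSpacing,probeLength probe grid in bp (defaults 100 / 50).
#' @param effectSize log2-ratio shift inside methylated domains
#'   (default 1.0).
#' @param hypoEffect magnitude of the negative shift inside hypomethylated
#'   domains (default 1.0).
#' @param noiseSd per-probe Gaussian noise sd `sigma` (default 0.3).
#' @param replicateSharedFraction fraction `rho` of noise variance shared
#'   between replicates (default 0.8).
#' @param fractionMethylated named per-stage fractions of methylated genes
#'   (defaults from the reported methylated-gene counts: 0.324 pre-MBT,
#'   0.449 at the MBT, 0.47 post-MBT).
#' @param fractionHypomethylated fraction of hypomethylated genes
#'   (default 0.41, the reported hypomethylated-promoter fraction);
#'   disjoint from the methylated set.
#' @param fractionHcp marginal fraction of high-CpG promoters
#'   (default 0.65).
#' @param hcpProbHypo probability that a hypomethylated-truth gene is an
#'   HCP (default 0.8, the reported "nearly 80%" association); the
#'   non-hypomethylated genes are adjusted so the marginal stays
#'   `fractionHcp`.
#' @param methylLocationProbs probabilities of the three methylated-domain
#'   placements `up_only` (rel. -900/-100), `down_only` (+100/+900) and
#'   `tss` (-400/+400).
#' @param hypoDomain TSS-relative extent of hypomethylated domains
#'   (default `c(-1400, 400)`: covers the -1/0 kb call window plus one
#'   KS-window margin on each side).
#' @param cohortMixture cohort label probabilities (defaults proportional
#'   to the 733/608/438/2990 maternal-degraded / maternal-zygotic /
#'   zygotic / undetected cohort sizes).
#' @param markLogOdds per-mark logistic coefficients
#'   (`intercept`, `methylated`, `hypomethylated`) generating histone-mark
#'   flags from the methylation state.
#' @param expressionLogOdds coefficients (`intercept`, `mark`,
#'   `methylated`, `hypomethylated`) for the post-ZGA expression flag;
#'   `mark` applies per present mark.
#' @param cohortExpressionLogOdds per-cohort additive term for the
#'   expression flag.
#' @param genesPerChrom genes per simulated chromosome (default 50).
#' @param interGeneGap gap between tiled regions in bp (default 10000).
#' @param seed integer master seed; every simulate* function derives its
#'   stream deterministically from it.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 1000L,
                             tileRange = c(-15000, 5000),
                             probeSpacing = 100L, probeLength = 50L,
                             effectSize = 1.0, hypoEffect = 1.0,
                             noiseSd = 0.3,
                             replicateSharedFraction = 0.8,
                             fractionMethylated = c(pre_mbt = 0.324,
                                                    mbt = 0.449,
                                                    post_mbt = 0.470),
                             fractionHypomethylated = 0.41,
                             fractionHcp = 0.65, hcpProbHypo = 0.80,
                             methylLocationProbs = c(up_only = 0.35,
                                                     down_only = 0.35,
                                                     tss = 0.30),
                             hypoDomain = c(-1400, 400),
                             cohortMixture = c(maternal_degraded = 733,
                                               maternal_zygotic = 608,
                                               zygotic = 438,
                                               undetected = 2990) / 4769,
                             markLogOdds = list(
                               h3k4me3 = c(intercept = -0.5,
                                           methylated = -0.5,
                                           hypomethylated = 2.0),
                               h3k9me3 = c(intercept = -1.5,
                                           methylated = 2.0,
                                           hypomethylated = -1.0),
                               h3k27me3 = c(intercept = -1.0,
                                            methylated = 0.0,
                                            hypomethylated = 0.0)),
                             expressionLogOdds = c(intercept = -1.0,
                                                   mark = 1.0,
                                                   methylated = -0.3,
                                                   hypomethylated = 1.0),
                             cohortExpressionLogOdds = c(
                               maternal_degraded = -1.0,
                               maternal_zygotic = 2.0, zygotic = 2.0,
                               undetected = -2.0),
                             genesPerChrom = 50L, interGeneGap = 10000L,
                             seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), tileRange = tileRange,
              probeSpacing = as.integer(probeSpacing),
              probeLength = as.integer(probeLength),
              effectSize = effectSize, hypoEffect = hypoEffect,
              noiseSd = noiseSd,
              replicateSharedFraction = replicateSharedFraction,
              fractionMethylated = fractionMethylated,
              fractionHypomethylated = fractionHypomethylated,
              fractionHcp = fractionHcp, hcpProbHypo = hcpProbHypo,
              methylLocationProbs = methylLocationProbs,
              hypoDomain = hypoDomain, cohortMixture = cohortMixture,
              markLogOdds = markLogOdds,
              expressionLogOdds = expressionLogOdds,
              cohortExpressionLogOdds = cohortExpressionLogOdds,
              genesPerChrom = as.integer(genesPerChrom),
              interGeneGap = as.integer(interGeneGap),
              seed = as.integer(seed))
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  fr <- c(cfg$fractionMethylated, cfg$fractionHypomethylated,
          cfg$fractionHcp, cfg$hcpProbHypo, cfg$cohortMixture,
          cfg$replicateSharedFraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (max(cfg$fractionMethylated) + cfg$fractionHypomethylated > 1)
    stop("methylated + hypomethylated fractions exceed 1 at some stage")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  if (cfg$probeSpacing <= 0) stop("probeSpacing must be > 0")
  if (cfg$tileRange[1] >= cfg$tileRange[2]) stop("invalid tileRange")
  if (abs(sum(cfg$cohortMixture) - 1) > 1e-8)
    stop("cohortMixture must sum to 1")
  invisible(TRUE)
}

# Deterministic sub-seeds: each simulation stream gets its own seed
# derived from the master seed, kept below 2^31.
subSeed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

stageIndex <- function(cfg, stage) {
  idx <- match(stage, names(cfg$fractionMethylated))
  if (is.na(idx)) stop("unknown stage: ", stage)
  idx
}

#' Plant the per-gene truth and emit promoter sequences
#'
#' Draws the full gene-state skeleton (methylation state per stage,
#' hypomethylation flag, domain placement, CpG class, gene placement on
#' simulated chromosomes) and generates a 1-kb upstream promoter sequence
#' per gene consistent with the planted CpG class: HCP-truth genes carry a
#' planted 500-bp CpG-island segment (o/e CG ratio >= 0.8 and CG content
#' >= 0.5, comfortably above the 0.65/0.30 calling thresholds), LCP-truth
#' genes are CpG-depleted throughout (every 500-bp window o/e <= 0.4).
#' Each sequence is verified against [classifyPromoter()] at step 1 and
#' resampled on violation, so the emitted truth is exact by construction.
#'
#' @param cfg a [simulationConfig()].
#' @return list: `sequences` (named `DNAStringSet`, one 1-kb upstream
#'   region per gene), `annotation` (promoter `GRanges`), `truth`
#'   (`data.frame` with planted states and domain coordinates).
#' @export
simulatePromoterSequences <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(subSeed(cfg$seed, 1))
  n <- cfg$nGenes
  ids <- sprintf("gene%05d", seq_len(n))
  stages <- names(cfg$fractionMethylated)

  # placement: genes laid out along chromosomes, alternating strands,
  # tiled regions separated by interGeneGap
  stride <- (cfg$tileRange[2] - cfg$tileRange[1]) + cfg$interGeneGap
  pos_in_chrom <- (seq_len(n) - 1L) %% cfg$genesPerChrom
  chrom <- paste0("chr", 1L + (seq_len(n) - 1L) %/% cfg$genesPerChrom)
  strand <- rep(c("+", "-"), length.out = n)
  # every tiled region occupies [1000 + pos*stride, 1000 + pos*stride +
  # width) regardless of strand, so regions never overlap
  tss <- 1000 + pos_in_chrom * stride +
    ifelse(strand == "-", cfg$tileRange[2], -cfg$tileRange[1])

  # latent maintenance variable: methylated at stage s iff u < fraction_s,
  # so the per-stage methylated sets are nested; hypomethylated genes are
  # the top fractionHypomethylated slice, disjoint from all methylated sets
  u <- runif(n)
  meth <- vapply(cfg$fractionMethylated, function(f) u < f, logical(n))
  colnames(meth) <- stages
  hypo <- u >= 1 - cfg$fractionHypomethylated
  if (max(cfg$fractionMethylated) > 1 - cfg$fractionHypomethylated)
    stop("state fractions overlap")  # guarded in the config too
  ever_meth <- meth[, which.max(cfg$fractionMethylated)]

  loc <- rep("none", n)
  loc[ever_meth] <- sample(names(cfg$methylLocationProbs),
                           sum(ever_meth), replace = TRUE,
                           prob = cfg$methylLocationProbs)
  dom <- matrix(NA_real_, n, 2)
  dom[loc == "up_only", ] <- rep(c(-900, -100), each = sum(loc == "up_only"))
  dom[loc == "down_only", ] <- rep(c(100, 900), each = sum(loc == "down_only"))
  dom[loc == "tss", ] <- rep(c(-400, 400), each = sum(loc == "tss"))

  # CpG class: HCP probability raised for hypomethylated-truth genes,
  # compensated elsewhere to keep the configured marginal
  p_other <- (cfg$fractionHcp -
                cfg$fractionHypomethylated * cfg$hcpProbHypo) /
    max(1e-12, 1 - cfg$fractionHypomethylated)
  p_other <- min(1, max(0, p_other))
  p_hcp <- ifelse(hypo, cfg$hcpProbHypo, p_other)
  is_hcp <- runif(n) < p_hcp

  seqs <- character(n)
  for (g in seq_len(n)) {
    seqs[g] <- samplePromoterSequence(is_hcp[g])
  }

  truth <- data.frame(gene_id = ids, chrom = chrom, tss = tss,
                      strand = strand,
                      cpg_class_true = ifelse(is_hcp, "HCP", "LCP"),
                      hypomethylated_true = hypo,
                      location_true = loc,
                      domain_lo = dom[, 1], domain_hi = dom[, 2],
                      hypo_lo = ifelse(hypo, cfg$hypoDomain[1], NA_real_),
                      hypo_hi = ifelse(hypo, cfg$hypoDomain[2], NA_real_),
                      stringsAsFactors = FALSE)
  for (s in stages) truth[[paste0("methylated_true_", s)]] <- meth[, s]

  sequences <- DNAStringSet(setNames(seqs, ids))
  ann <- promoterAnnotation(ids, chrom, tss, strand)
  list(sequences = sequences, annotation = ann, truth = truth)
}

# One 1-kb promoter sequence of the requested class, verified against the
# step-1 classifier and resampled on violation.
samplePromoterSequence <- function(hcp, len = 1000L, island = 500L,
                                   maxTries = 50L) {
  for (try in seq_len(maxTries)) {
    if (hcp) {
      offset <- sample.int(len - island + 1L, 1L) - 1L
      seqstr <- paste0(sampleDinucleotide(offset, cg_rich = FALSE),
                       sampleDinucleotide(island, cg_rich = TRUE),
                       sampleDinucleotide(len - island - offset,
                                          cg_rich = FALSE))
      isl <- substr(seqstr, offset + 1L, offset + island)
      ok <- oeCgRatio(isl) >= 0.8 && cgContent(isl) >= 0.5 &&
        classifyPromoter(seqstr)$class == "HCP"
    } else {
      seqstr <- sampleDinucleotide(len, cg_rich = FALSE)
      cp <- classifyPromoter(seqstr)
      # cp$best_oe is the maximal window o/e when no window qualifies
      ok <- cp$class == "LCP" && cp$best_oe <= 0.4
    }
    if (ok) return(seqstr)
  }
  stop("could not realise the requested promoter composition; ",
       "composition constraints look infeasible")
}

# First-order Markov base sampler with controllable CpG suppression:
# CG-rich blocks use island composition (C/G-heavy, CpG not suppressed);
# depleted blocks use AT-leaning composition with P(G | C) shrunk by the
# suppression factor, the defining low-CpG-promoter property.
sampleDinucleotide <- function(len, cg_rich) {
  if (len <= 0L) return("")
  bases <- c("A", "C", "G", "T")
  if (cg_rich) {
    p <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2); suppress <- 1.0
  } else {
    p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3); suppress <- 0.2
  }
  trans <- rbind(A = p, C = p, G = p, T = p)
  trans["C", "G"] <- p["G"] * suppress
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1L, cumsum))
  u <- runif(len)
  state <- integer(len)
  state[1] <- findInterval(u[1], cumsum(p)) + 1L
  if (len > 1L) for (i in 2:len)
    state[i] <- findInterval(u[i], cum[state[i - 1L], ]) + 1L
  paste(bases[state], collapse = "")
}

#' Simulate the tiled MeDIP experiment for one stage
#'
#' Lays probes of length `probeLength` every `probeSpacing` bp across the
#' tiled range of every gene (strand-aware), and draws duplicate MeDIP
#' log2 ratios: `effectSize` inside planted methylated domains, minus
#' `hypoEffect` inside hypomethylated domains, plus Gaussian noise of
#' which a fraction `rho` of the variance is shared between the two
#' replicates.  Output is deterministic given the config seed and stage.
#'
#' @param cfg a [simulationConfig()].
#' @param truth truth table from [simulatePromoterSequences()].
#' @param stage stage name (must appear in `cfg$fractionMethylated`).
#' @return list of two [ProbeSet-class] replicates (`rep1`, `rep2`).
#' @export
simulateTilingExperiment <- function(cfg, truth, stage) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  sidx <- stageIndex(cfg, stage)
  set.seed(subSeed(cfg$seed, 100 + sidx))
  n <- nrow(truth)
  rel_start <- seq(cfg$tileRange[1], cfg$tileRange[2] - cfg$probeLength,
                   by = cfg$probeSpacing)
  rel_mid <- rel_start + cfg$probeLength / 2
  k <- length(rel_start)

  meth_col <- paste0("methylated_true_", stage)
  if (!meth_col %in% names(truth)) stop("truth lacks column ", meth_col)

  chrom <- rep(truth$chrom, each = k)
  minus <- rep(truth$strand == "-", each = k)
  tss <- rep(truth$tss, each = k)
  rs <- rep(rel_start, n); rm <- rep(rel_mid, n)
  start0 <- ifelse(minus, tss - rs - cfg$probeLength, tss + rs)
  end0 <- start0 + cfg$probeLength

  in_dom <- rep(truth[[meth_col]], each = k) &
    !is.na(rep(truth$domain_lo, each = k)) &
    rm >= rep(truth$domain_lo, each = k) &
    rm < rep(truth$domain_hi, each = k)
  in_hypo <- rep(truth$hypomethylated_true, each = k) &
    rm >= rep(ifelse(is.na(truth$hypo_lo), Inf, truth$hypo_lo), each = k) &
    rm < rep(ifelse(is.na(truth$hypo_hi), -Inf, truth$hypo_hi), each = k)

  signal <- cfg$effectSize * in_dom - cfg$hypoEffect * in_hypo
  rho <- cfg$replicateSharedFraction
  shared <- rnorm(n * k, sd = cfg$noiseSd * sqrt(rho))
  r1 <- signal + shared + rnorm(n * k, sd = cfg$noiseSd * sqrt(1 - rho))
  r2 <- signal + shared + rnorm(n * k, sd = cfg$noiseSd * sqrt(1 - rho))

  list(rep1 = ProbeSet(chrom, start0, end0, r1, "rep1", stage),
       rep2 = ProbeSet(chrom, start0, end0, r2, "rep2", stage))
}

#' Simulate cohort labels, histone-mark flags and expression flags
#'
#' Cohort labels are multinomial draws from the configured mixture.  Mark
#' flags follow per-mark logistic models on the planted methylation state
#' at the given stage; the post-ZGA expression flag follows a logistic
#' model with cohort base rates, a per-present-mark term and methylation
#' terms.  With all log-odds zero the table is an exact global null for
#' the integration statistics.
#'
#' @inheritParams simulateTilingExperiment
#' @param stage stage whose planted methylation state drives the mark
#'   models.
#' @return a gene feature table `data.frame`: `gene_id`, `cohort`,
#'   `cpg_class`, `methylated_<stage>`, `hypomethylated_<stage>`, one
#'   logical column per mark (`<mark>_<stage>`), and
#'   `expressed_post_zga`.
#' @export
simulateCohortsAndMarks <- function(cfg, truth, stage) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  sidx <- stageIndex(cfg, stage)
  set.seed(subSeed(cfg$seed, 200 + sidx))
  n <- nrow(truth)
  meth <- truth[[paste0("methylated_true_", stage)]]
  hypo <- truth$hypomethylated_true
  cohort <- sample(names(cfg$cohortMixture), n, replace = TRUE,
                   prob = cfg$cohortMixture)
  gft <- data.frame(gene_id = truth$gene_id, cohort = cohort,
                    cpg_class = truth$cpg_class_true,
                    stringsAsFactors = FALSE)
  gft[[paste0("methylated_", stage)]] <- meth
  gft[[paste0("hypomethylated_", stage)]] <- hypo
  n_marks <- 0
  for (mk in names(cfg$markLogOdds)) {
    b <- cfg$markLogOdds[[mk]]
    eta <- b["intercept"] + b["methylated"] * meth +
      b["hypomethylated"] * hypo
    gft[[paste0(mk, "_", stage)]] <- runif(n) < plogis_(eta)
  }
  marks_present <- rowSums(as.matrix(
    gft[paste0(names(cfg$markLogOdds), "_", stage)]))
  e <- cfg$expressionLogOdds
  eta <- e["intercept"] + e["mark"] * marks_present +
    e["methylated"] * meth + e["hypomethylated"] * hypo +
    cfg$cohortExpressionLogOdds[cohort]
  gft$expressed_post_zga <- runif(n) < plogis_(eta)
  gft
}

plogis_ <- function(eta) 1 / (1 + exp(-as.numeric(eta)))

#' Simulate a complete multi-stage MeDIP experiment
#'
#' Convenience wrapper: promoter sequences and truth, duplicate probe sets
#' per requested stage, and the gene feature table for the stage driving
#' the integration analyses.
#'
#' @param cfg a [simulationConfig()].
#' @param stages stages to tile (default: all configured stages).
#' @param gftStage stage for the gene feature table (default: last of
#'   `stages`).
#' @return list with `config`, `sequences`, `annotation`, `truth`,
#'   `probes` (per stage: list of `rep1`/`rep2` [ProbeSet-class]s), and
#'   `gft`.
#' @export
simulateMedipExperiment <- function(cfg,
                                    stages = names(cfg$fractionMethylated),
                                    gftStage = stages[length(stages)]) {
  base <- simulatePromoterSequences(cfg)
  probes <- lapply(stages, function(s)
    simulateTilingExperiment(cfg, base$truth, s))
  names(probes) <- stages
  gft <- simulateCohortsAndMarks(cfg, base$truth, gftStage)
  list(config = cfg, sequences = base$sequences,
       annotation = base$annotation, truth = base$truth, probes = probes,
       gft = gft)
}
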