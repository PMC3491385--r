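test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- simulationConfig(nGenes = 40, seed = 99)
  a <- simulateMedipExperiment(cfg, stages = "pre_mbt",
                               gftStage = "pre_mbt")
  b <- simulateMedipExperiment(cfg, stages = "pre_mbt",
                               gftStage = "pre_mbt")
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth, b$truth)
  expect_identical(probeRatios(a$probes$pre_mbt$rep1),
                   probeRatios(b$probes$pre_mbt$rep1))
  expect_identical(a$gft, b$gft)

  c2 <- simulateMedipExperiment(simulationConfig(nGenes = 40, seed = 100),
                                stages = "pre_mbt", gftStage = "pre_mbt")
  expect_false(identical(probeRatios(a$probes$pre_mbt$rep1),
                         probeRatios(c2$probes$pre_mbt$rep1)))
})

test_that("planted CpG classes are recovered perfectly by construction", {
  all_h <- simulatePromoterSequences(simulationConfig(nGenes = 30,
                                                      fractionHcp = 1,
                                                      hcpProbHypo = 1,
                                                      seed = 3))
  expect_true(all(classifyPromoters(all_h$sequences)$class == "HCP"))

  all_l <- simulatePromoterSequences(simulationConfig(nGenes = 30,
                                                      fractionHcp = 0,
                                                      hcpProbHypo = 0,
                                                      seed = 3))
  expect_true(all(classifyPromoters(all_l$sequences)$class == "LCP"))

  mix <- simulatePromoterSequences(simulationConfig(nGenes = 120,
                                                    seed = 13))
  called <- classifyPromoters(mix$sequences)
  expect_identical(called$class, mix$truth$cpg_class_true)
})

test_that("noiseless probes take exactly the planted values", {
  cfg <- simulationConfig(nGenes = 30, noiseSd = 0, seed = 8)
  base <- simulatePromoterSequences(cfg)
  reps <- simulateTilingExperiment(cfg, base$truth, "mbt")
  r <- probeRatios(reps$rep1)
  expect_true(all(r %in% c(0, 1, -1)))
  expect_identical(probeRatios(reps$rep1), probeRatios(reps$rep2))

  # locate one methylated gene and check its domain probes read Delta
  t_m <- base$truth[base$truth$methylated_true_mbt &
                      base$truth$location_true == "tss", ][1, ]
  ann <- base$annotation[t_m$gene_id]
  mp <- mapProbesToPromoter(reps$rep1, ann, c(t_m$domain_lo, t_m$domain_hi))
  expect_true(all(mp$ratio == 1))
  out <- mapProbesToPromoter(reps$rep1, ann, c(2000, 4000))
  expect_true(all(out$ratio == 0))

  t_h <- base$truth[base$truth$hypomethylated_true, ][1, ]
  hp <- mapProbesToPromoter(reps$rep1, base$annotation[t_h$gene_id],
                            c(-1000, 0))
  expect_true(all(hp$ratio == -1))
})

test_that("planted domains are visible above the noise floor", {
  cfg <- simulationConfig(nGenes = 60, seed = 21)
  base <- simulatePromoterSequences(cfg)
  reps <- simulateTilingExperiment(cfg, base$truth, "post_mbt")
  tr <- base$truth
  meth <- which(tr$methylated_true_post_mbt)
  for (g in meth[1:10]) {
    mp <- mapProbesToPromoter(reps$rep1, base$annotation[g],
                              c(tr$domain_lo[g], tr$domain_hi[g]))
    expect_gte(mean(mp$ratio),
               cfg$effectSize - 3 * cfg$noiseSd / sqrt(nrow(mp)))
  }
})

test_that("methylated sets are nested across stages, hypomethylation fixed", {
  cfg <- simulationConfig(nGenes = 300, seed = 27)
  tr <- simulatePromoterSequences(cfg)$truth
  expect_true(all(!tr$methylated_true_pre_mbt | tr$methylated_true_mbt))
  expect_true(all(!tr$methylated_true_mbt | tr$methylated_true_post_mbt))
  expect_true(all(!(tr$hypomethylated_true &
                      tr$methylated_true_post_mbt)))
  # per-stage fractions near their configuration
  expect_equal(mean(tr$methylated_true_pre_mbt),
               cfg$fractionMethylated[["pre_mbt"]], tolerance = 0.1)
  expect_equal(mean(tr$hypomethylated_true),
               cfg$fractionHypomethylated, tolerance = 0.1)
})

test_that("probe-level replicate correlation follows the closed form", {
  cfg <- simulationConfig(nGenes = 150, seed = 31)
  base <- simulatePromoterSequences(cfg)
  reps <- simulateTilingExperiment(cfg, base$truth, "mbt")
  r1 <- probeRatios(reps$rep1); r2 <- probeRatios(reps$rep2)
  # var((r1+r2)/2) = v_sig + (1+rho)/2 * sigma^2, solve for v_sig
  v_sig <- stats::var((r1 + r2) / 2) - cfg$noiseSd^2 *
    (1 + cfg$replicateSharedFraction) / 2
  expected <- (v_sig + cfg$replicateSharedFraction * cfg$noiseSd^2) /
    (v_sig + cfg$noiseSd^2)
  expect_equal(cor(r1, r2), expected, tolerance = 0.02)
})

test_that("cohort labels follow the configured mixture", {
  cfg <- simulationConfig(nGenes = 2000, seed = 35)
  base <- simulatePromoterSequences(cfg)
  gft <- simulateCohortsAndMarks(cfg, base$truth, "mbt")
  counts <- table(factor(gft$cohort, names(cfg$cohortMixture)))
  gof <- stats::chisq.test(counts, p = cfg$cohortMixture)
  expect_gt(gof$p.value, 1e-3)
})

test_that("planted mark association is detected by the integration stats", {
  cfg <- simulationConfig(nGenes = 2000, seed = 39)
  base <- simulatePromoterSequences(cfg)
  gft <- simulateCohortsAndMarks(cfg, base$truth, "mbt")
  res <- markByMethylationTable(gft, "mbt")
  # h3k4me3 is planted with +2 log-odds on hypomethylated promoters
  expect_lt(res$tests$h3k4me3$p_value, 0.01)
  p4 <- res$proportions[res$proportions$mark == "h3k4me3", ]
  expect_gt(p4$prop_hypomethylated, p4$prop_methylated)
  # h3k9me3 is planted the other way around
  p9 <- res$proportions[res$proportions$mark == "h3k9me3", ]
  expect_gt(p9$prop_methylated, p9$prop_hypomethylated)
})

test_that("a null mark model yields calibrated tests", {
  cfg0 <- simulationConfig(nGenes = 500,
                           markLogOdds = list(
                             h3k4me3 = c(intercept = 0, methylated = 0,
                                         hypomethylated = 0),
                             h3k9me3 = c(intercept = -1, methylated = 0,
                                         hypomethylated = 0),
                             h3k27me3 = c(intercept = -1, methylated = 0,
                                          hypomethylated = 0)),
                           seed = 43)
  base <- simulatePromoterSequences(cfg0)
  rejections <- 0; tests <- 0
  for (s in 1:25) {
    cfg0$seed <- 43 + s
    gft <- simulateCohortsAndMarks(cfg0, base$truth, "mbt")
    res <- markByMethylationTable(gft, "mbt")
    for (t in res$tests) {
      tests <- tests + 1
      rejections <- rejections + (t$p_value <= 0.05)
    }
  }
  expect_lt(rejections / tests, 0.12)
})

test_that("invalid configurations are refused", {
  expect_error(simulationConfig(fractionHypomethylated = 1.4), "fraction")
  expect_error(simulationConfig(fractionMethylated = c(pre_mbt = 0.7,
                                                       mbt = 0.7,
                                                       post_mbt = 0.7),
                                fractionHypomethylated = 0.41), "exceed")
  expect_error(simulationConfig(probeSpacing = 0), "probeSpacing")
  expect_error(simulationConfig(noiseSd = -1), "noiseSd")
})
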