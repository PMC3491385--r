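#' Run configuration for the end-to-end pipeline
#'
#' Bundles the analysis thresholds (all defaults are the published
#' operating constants: 750-bp KS window, probe p cutoff 0.01 with >= 2
#' consecutive probes, hypomethylation floor 0.99 over the -1/0 kb window,
#' the -5/+1 kb analysis region, and the 500-bp / o/e 0.65 / CG 0.30
#' promoter classification) with the simulation configuration and output
#' location.  Can be round-tripped through YAML.
#'
#' @param sim a [simulationConfig()] describing the input experiment.
#' @param stages stages to analyse (default: all configured ones).
#' @param windowBp KS scoring window (bp).
#' @param pCutoff,minProbes peak-calling constants.
#' @param maxGapBp run-breaking gap for peaks.
#' @param region,upWindow,downWindow,hypoWindow TSS-relative windows.
#' @param hypoFloor per-probe p floor for the hypomethylation call.
#' @param minProbesPresent minimum window probes for a hypomethylation
#'   call.
#' @param cgWindowBp,cgStepBp,oeMin,cgMin promoter classification scan.
#' @param metageneRange,metageneBinBp metagene profiling window and bin.
#' @param outDir output directory (`NULL`: nothing written).
#' @param seed master seed; overrides `sim$seed` so one integer controls
#'   the whole run.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(sim = simulationConfig(), stages = NULL,
                      windowBp = 750, pCutoff = 0.01, minProbes = 2L,
                      maxGapBp = 1000, region = c(-5000, 1000),
                      upWindow = c(-1000, 0), downWindow = c(0, 1000),
                      hypoWindow = c(-1000, 0), hypoFloor = 0.99,
                      minProbesPresent = 3L, cgWindowBp = 500L,
                      cgStepBp = 1L, oeMin = 0.65, cgMin = 0.30,
                      metageneRange = c(-2000, 2000),
                      metageneBinBp = 100, outDir = NULL, seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (is.null(stages)) stages <- names(sim$fractionMethylated)
  stopifnot(pCutoff > 0, pCutoff <= 1, hypoFloor > 0, hypoFloor <= 1,
            minProbes >= 1, windowBp > 0)
  structure(list(sim = sim, stages = stages, windowBp = windowBp,
                 pCutoff = pCutoff, minProbes = as.integer(minProbes),
                 maxGapBp = maxGapBp, region = region,
                 upWindow = upWindow, downWindow = downWindow,
                 hypoWindow = hypoWindow, hypoFloor = hypoFloor,
                 minProbesPresent = as.integer(minProbesPresent),
                 cgWindowBp = as.integer(cgWindowBp),
                 cgStepBp = as.integer(cgStepBp), oeMin = oeMin,
                 cgMin = cgMin, metageneRange = metageneRange,
                 metageneBinBp = metageneBinBp, outDir = outDir,
                 seed = sim$seed),
            class = "RunConfig")
}

#' Execute the full promoter-methylation pipeline
#'
#' Simulates (or accepts) the tiled MeDIP experiment, then runs
#' normalization, windowed KS scoring, peak calling, promoter
#' methylation / location / hypomethylation calls per stage, promoter
#' CpG classification, stage transitions, and the integration statistics
#' (CpG-class enrichment among hypomethylated promoters, histone marks by
#' methylation stratum, expression by mark and methylation state).  When
#' `config$outDir` is set, all tables are written as TSV/JSON together
#' with a provenance record (config echo, seed, package version, file
#' checksums) and a deterministic `report_hash`.
#'
#' @param config a [runConfig()].
#' @param experiment optional pre-built experiment (the structure returned
#'   by [simulateMedipExperiment()]); by default one is simulated from
#'   `config$sim`.
#' @return list with `calls` (per-stage call tables), `peaks`,
#'   `profiles`, `cpg` (classification table), `transitions`,
#'   `integration`, `metagene`, `experiment`, `provenance` and
#'   `report_hash`.
#' @export
runPipeline <- function(config, experiment = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(experiment))
    experiment <- simulateMedipExperiment(config$sim,
                                          stages = config$stages)
  ann <- experiment$annotation
  calls <- list(); peaks <- list(); profiles <- list()
  for (s in config$stages) {
    reps <- experiment$probes[[s]]
    ps1 <- normalizeCenter(reps$rep1)
    ps2 <- normalizeCenter(reps$rep2)
    pr1 <- ksProbeScores(ps1, windowBp = config$windowBp)
    pr2 <- ksProbeScores(ps2, windowBp = config$windowBp)
    pk1 <- callPeaks(pr1, config$pCutoff, config$minProbes, config$maxGapBp)
    pk2 <- callPeaks(pr2, config$pCutoff, config$minProbes, config$maxGapBp)
    calls[[s]] <- callMethylationTable(ann, pk1, pk2, pr1, pr2, stage = s,
                                       region = config$region,
                                       upWindow = config$upWindow,
                                       downWindow = config$downWindow,
                                       hypoWindow = config$hypoWindow,
                                       pFloor = config$hypoFloor,
                                       minProbesPresent =
                                         config$minProbesPresent)
    peaks[[s]] <- list(rep1 = pk1, rep2 = pk2)
    profiles[[s]] <- list(rep1 = pr1, rep2 = pr2,
                          ps1 = ps1, ps2 = ps2)
  }

  cpg <- classifyPromoters(experiment$sequences,
                           windowBp = config$cgWindowBp,
                           stepBp = config$cgStepBp, oeMin = config$oeMin,
                           cgMin = config$cgMin)
  transitions <- if (length(config$stages) >= 2)
    stageTransitions(calls, config$stages) else NULL

  last <- config$stages[length(config$stages)]
  lastcall <- calls[[last]]
  gft <- experiment$gft
  gft$cpg_class <- cpg$class[match(gft$gene_id, cpg$gene_id)]
  mcol <- paste0("methylated_", last)
  hcol <- paste0("hypomethylated_", last)
  gft[[mcol]] <- lastcall$methylated
  gft[[hcol]] <- lastcall$hypomethylated == "yes"

  hypo_genes <- lastcall$gene_id[lastcall$hypomethylated == "yes"]
  integration <- list(
    hcp_in_hypomethylated = if (length(hypo_genes))
      proportionEnrichment(hypo_genes, cpg$gene_id,
                           setNames(cpg$class == "HCP", cpg$gene_id))
      else NULL,
    marks = markByMethylationTable(gft, last),
    expression = expressionByMarkAndMethylation(gft, last))

  metagene <- tryCatch(
    metageneProfile(ann, profiles[[last]]$ps1, profiles[[last]]$ps2,
                    profiles[[last]]$rep1, profiles[[last]]$rep2,
                    range = config$metageneRange,
                    binBp = config$metageneBinBp),
    error = function(e) NULL)

  result <- list(calls = calls, peaks = peaks, profiles = profiles,
                 cpg = cpg, transitions = transitions,
                 integration = integration, metagene = metagene,
                 experiment = experiment)
  result$provenance <- list(
    package_version = as.character(utils::packageVersion("medipromo")),
    seed = config$seed,
    config = configAsList(config))
  if (!is.null(config$outDir))
    result <- writePipelineOutputs(result, config)
  result$report_hash <- reportHash(result)
  result
}

configAsList <- function(config) {
  cl <- unclass(config)
  cl$sim <- unclass(cl$sim)
  # named vectors become YAML maps (write_yaml drops names of atomic
  # vectors), so names survive the round trip
  for (f in c("fractionMethylated", "methylLocationProbs",
              "cohortMixture", "expressionLogOdds",
              "cohortExpressionLogOdds"))
    cl$sim[[f]] <- as.list(cl$sim[[f]])
  cl$sim$markLogOdds <- lapply(cl$sim$markLogOdds, as.list)
  cl
}

#' Read/write a run configuration as YAML
#'
#' @param config a [runConfig()].
#' @param path YAML file.
#' @return `readRunConfigYaml` returns a `RunConfig`;
#'   `writeRunConfigYaml` returns `path` invisibly.
#' @export
writeRunConfigYaml <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}

#' @rdname writeRunConfigYaml
#' @export
readRunConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  simargs$fractionMethylated <- unlist(simargs$fractionMethylated)
  simargs$cohortMixture <- unlist(simargs$cohortMixture)
  simargs$methylLocationProbs <- unlist(simargs$methylLocationProbs)
  simargs$markLogOdds <- lapply(simargs$markLogOdds, unlist)
  simargs$expressionLogOdds <- unlist(simargs$expressionLogOdds)
  simargs$cohortExpressionLogOdds <- unlist(simargs$cohortExpressionLogOdds)
  sim <- do.call(simulationConfig, simargs)
  keep <- setdiff(names(y), c("sim", "seed"))
  do.call(runConfig, c(list(sim = sim), y[keep]))
}

writePipelineOutputs <- function(result, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  files <- character()
  for (s in names(result$calls)) {
    f <- out(paste0("calls_", s, ".tsv"))
    write.table(result$calls[[s]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
    for (r in c("rep1", "rep2")) {
      f <- out(paste0("peaks_", s, "_", r, ".bed"))
      writePeaksBed(result$peaks[[s]][[r]], f)
      files <- c(files, f)
      f <- out(paste0("ks_", s, "_", r, ".tsv"))
      writeKSProfile(result$profiles[[s]][[r]], f)
      files <- c(files, f)
    }
  }
  f <- out("cpg_classes.tsv")
  write.table(result$cpg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(result$transitions)) {
    f <- out("stage_transitions.tsv")
    write.table(result$transitions$transitions, f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- out("stage_counts.json")
    jsonlite::write_json(as.list(result$transitions$counts), f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  if (!is.null(result$metagene)) {
    f <- out("metagene.tsv")
    write.table(result$metagene, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  f <- out("integration.json")
  jsonlite::write_json(integrationAsJson(result$integration), f,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- out("provenance.yaml")
  yaml::write_yaml(result$provenance, f)
  files <- c(files, f)
  result$files <- files
  result
}

integrationAsJson <- function(integration) {
  simplify <- function(cr) if (is.null(cr)) NULL else
    list(p_value = cr$p_value, odds_ratio = cr$odds_ratio, test = cr$test)
  list(
    hcp_in_hypomethylated = if (!is.null(integration$hcp_in_hypomethylated))
      c(simplify(integration$hcp_in_hypomethylated$result),
        list(prop_feature = integration$hcp_in_hypomethylated$prop_feature,
             prop_background =
               integration$hcp_in_hypomethylated$prop_background)),
    mark_tests = lapply(integration$marks$tests, simplify),
    mark_proportions = integration$marks$proportions,
    expression_tests = lapply(integration$expression$tests, simplify),
    expression_cells = integration$expression$cells)
}

# Deterministic digest of the analysis outcome: md5 of the serialized
# call tables, peak intervals and classification table.
reportHash <- function(result) {
  core <- list(calls = result$calls,
               peaks = lapply(result$peaks, function(st)
                 lapply(st, function(pk)
                   data.frame(chrom = as.character(seqnames(pk)),
                              start = start(pk), end = end(pk),
                              n = mcols(pk)$n_probes))),
               cpg = result$cpg)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(core, tf, version = 2, compress = FALSE)
  unname(md5sum(tf))
}
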