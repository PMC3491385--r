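# medipromo

Promoter DNA methylation analysis for MeDIP tiling arrays, built around
the study design used for early zebrafish embryos: duplicate methylated-DNA
immunoprecipitations (MeDIP) hybridised to arrays that tile −15 kb to +5 kb
around the transcription start site (TSS) of each RefSeq promoter, read out
as log2 MeDIP/input ratios.  The package is aimed at epigenomics analysts
who want the complete calling chain — probe scoring through promoter calls
through integration statistics — as tested, seeded, reusable functions
rather than as a black-box array-vendor tool.

## What it computes

**Probe scoring.** After centering log2 ratios on zero, a 750-bp window is
placed around each consecutive probe and a one-sided two-sample
Kolmogorov–Smirnov test compares the window against the array background.
The statistic is

    D+ = sup_x [ F_bg(x) − F_win(x) ]

(window stochastically larger = local MeDIP enrichment), and each probe's
score is the p-value of its window: at array scale the one-sided asymptotic
form `p = exp(−2 D+² mn/(m+n))`, and the exact lattice-path null
probability (or a permutation oracle) at small sample sizes.

**Peak and promoter calls.** Peaks are maximal runs of ≥ 2 consecutive
probes with p ≤ 0.01.  A promoter is *methylated* when its TSS-relative
window (−5/+1 kb analysis region; −1/0 kb and 0/+1 kb windows for the
upstream/downstream/TSS location categories) overlaps at least one peak in
**both** replicates.  A promoter is *hypomethylated* when **every** probe in
the −1/0 kb window scores p ≥ 0.99 in both replicates — confidently below
genome-average enrichment.

**Promoter classes.** Each 1-kb upstream sequence is scanned with a 500-bp
sliding window; a promoter is a high-CpG promoter (HCP) when some window
has observed/expected CpG ratio `(N_CpG · L)/(N_C · N_G) ≥ 0.65` **and** CG
content `(N_C + N_G)/L > 0.30` (the zebrafish-adapted Takai–Jones rule),
else a low-CpG promoter (LCP).

**Downstream.** TSS-anchored metagene profiles, median methylation levels,
stage-to-stage maintenance/gain/loss sets, CpG-island counting with
CGI-cluster flags, and contingency statistics (Fisher's exact test,
Yates-corrected chi-square, Venn overlap reports) linking methylation state
to histone marks, expression cohorts and promoter class.

**Synthetic experiments.** `simulationConfig()` + `simulateMedipExperiment()`
generate the whole experiment with planted truth — tiled probes with
methylated (+Δ) and hypomethylated (−Δ) domains, shared-plus-replicate
Gaussian noise, promoter sequences with controlled CpG composition, cohort
and histone-mark labels with configurable association — so every stage of
the pipeline can be validated against known answers, fully reproducibly
from one seed.

## Worked example

```r
library(medipromo)
cfg <- simulationConfig(nGenes = 200, seed = 42)
sim <- simulateMedipExperiment(cfg, stages = c("pre_mbt", "mbt"),
                               gftStage = "mbt")
ps1 <- normalizeCenter(sim$probes$mbt$rep1)
ps2 <- normalizeCenter(sim$probes$mbt$rep2)
profile1 <- ksProbeScores(ps1)
profile1
#> KSProfile: 40000 probes | window 750 bp | background exclude_window
#>   p <= 0.01: 898 probes (2.25%) | unscored: 0
```

898 of 40,000 probes (2.25%) score p ≤ 0.01 — the planted methylated
domains plus the expected sliver of null probes.  Peaks and promoter calls:

```r
peaks1 <- callPeaks(profile1)
peaks2 <- callPeaks(ksProbeScores(ps2))
calls <- callMethylationTable(sim$annotation, peaks1, peaks2,
                              profile1, ksProbeScores(ps2), stage = "mbt")
table(calls$category)
#>   up_only down_only  tss_both      none
#>        35        36        31        98
table(calls$hypomethylated)
#>     yes      no no_call
#>      78     122       0
```

102 promoters are methylated somewhere in the −1/+1 kb neighbourhood
(upstream-only, downstream-only, or astride the TSS) and 78 are
hypomethylated.  Are hypomethylated promoters CG-rich, as the biology says
they should be?

```r
cpg <- classifyPromoters(sim$sequences)
hypo <- calls$gene_id[calls$hypomethylated == "yes"]
enr <- proportionEnrichment(hypo, cpg$gene_id,
                            setNames(cpg$class == "HCP", cpg$gene_id))
enr$result
#> fisher_exact (two.sided): p = 0.0008761, odds ratio = 2.946
round(c(hypo = enr$prop_feature, all = enr$prop_background), 3)
#>  hypo   all
#> 0.782 0.640
```

78.2% of hypomethylated promoters are HCPs versus 64.0% of all promoters
(p ≈ 9 × 10⁻⁴) — the planted association, recovered through the entire
calling chain.  Against the generator's truth table the methylation call
scores `recall = 1.00, fpr = 0.020` on this dataset.

`runPipeline(runConfig(sim = cfg, outDir = "out"))` runs all of the above
per stage and writes the call tables, peaks (BED), KS profiles, promoter
classes, stage transitions, integration statistics and a provenance record
with a deterministic report hash.

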