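---
title: "Methods: windowed KS scoring, promoter methylation calls and the synthetic experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed KS scoring, promoter methylation calls and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipromo)
```

# The measurement and its model

MeDIP-chip assays promoter DNA methylation by immunoprecipitating
methylated DNA fragments and co-hybridising them with input DNA to tiling
arrays; each probe reports a log2 MeDIP/input ratio.  On TSS-anchored
promoter arrays (probes every ~100 bp across −15 kb to +5 kb around each
transcription start site), methylated regions appear as runs of locally
elevated ratios, unmethylated CG-rich regions as runs of depressed ratios,
and the bulk of the genome as ratio noise around the array median.

The analysis chain in this package mirrors that structure:

1. **Centering** (`normalizeCenter()`): per replicate, ratios are shifted
   so their median is zero.  The median is exactly idempotent and
   rank-preserving; a Tukey biweight option is provided for users who
   prefer the classical array estimator.  Everything downstream of
   centering that matters statistically is rank-based, so the choice of
   location estimator does not move any call.

2. **Windowed one-sided KS scoring** (`ksProbeScores()`): a 750-bp window
   around each consecutive probe is compared against the rest of the
   array with a one-sided two-sample Kolmogorov–Smirnov test.  The
   statistic is `D+ = sup_x [F_bg(x) − F_win(x)]`, which is large when the
   window's ratios are stochastically **larger** than background — the
   direction MeDIP enrichment moves them.  The per-probe score is the
   p-value of its window.

3. **Peak calling** (`callPeaks()`): peaks are maximal runs of at least
   two consecutive probes with p ≤ 0.01, in array order on a chromosome,
   with runs additionally broken when consecutive probe midpoints are more
   than 1 kb apart (so runs never bridge untiled gaps between promoter
   regions).

4. **Promoter calls** (`promoterMethylated()`, `callHypomethylated()`,
   `classifyMethylationLocation()`): a promoter is methylated when its
   TSS-relative window overlaps at least one peak *in both replicates*;
   the analysis region is −5/+1 kb, with −1/0 kb and 0/+1 kb windows
   defining upstream-only / downstream-only / TSS location categories.  A
   promoter is hypomethylated when *every* probe in the −1/0 kb window has
   p ≥ 0.99 in both replicates — i.e. every probe individually looks
   confidently non-enriched relative to the genome average.

5. **Promoter CpG classes** (`classifyPromoter()`): the 1-kb upstream
   sequence is scanned with a 500-bp window; the promoter is an HCP when
   some window reaches both an observed/expected CpG ratio
   `(N_CpG · L)/(N_C · N_G) ≥ 0.65` and a CG content strictly `> 0.30`,
   the Takai–Jones rule re-parameterised for the fish genome's CpG
   landscape, else an LCP.

6. **Integration** (`proportionEnrichment()`, `markByMethylationTable()`,
   `expressionByMarkAndMethylation()`, `setOverlapReport()`): 2×2
   contingency analyses (Fisher's exact test; Yates-corrected chi-square)
   linking methylation strata to histone marks, expression cohorts and
   CpG class, plus Venn-style overlap reports between stages or samples.

# The p-value: exact, asymptotic, permutation

`oneSidedKS()` exposes three p-value routes, and the choice is a real
modelling decision rather than a numerical detail.

* **Exact** (default when `m·n ≤ 10 000`, the `stats::ks.test()`
  convention): `P(D+ ≥ d)` computed by counting monotone lattice paths
  whose every prefix keeps `j/n − i/m < d`.  This is the reference answer
  at small sizes and agrees with a label-shuffle permutation test to
  within Monte-Carlo error.

* **Asymptotic** (`exp(−2 d² mn/(m+n))`, clamped to `(0, 1]`): the route
  used for array-scale probe scoring, where `n` is the number of
  background probes (~10⁵) and the exact recursion is unaffordable.  Two
  properties matter.  First, at the p ≤ 0.01 decision boundary it is
  conservative (the measured null fraction of probes at p ≤ 0.01 is below
  0.01), so peak calling errs against false enrichment.  Second, near
  `d = 0` it is *deliberately* blunt: any window whose `D+` is small —
  including every window drawn from a distribution at or below the
  background — gets p ≈ 1.  The hypomethylation rule ("all probes
  p ≥ 0.99") lives entirely in this regime.  A perfectly calibrated
  p-value would be uniform under the null and would essentially never
  satisfy p ≥ 0.99 at ten probes twice over; the operating range of the
  published rule presupposes the asymptotic form, and this package keeps
  it for scoring on purpose.

* **Permutation**: a seeded label-shuffle oracle (rank-based fast path for
  tie-free data), used in the test suite as the independent check on both
  other routes.

Windows holding fewer than 4 probes (`minWindowProbes`) are not scored:
they get p = 1 and a `no_score` flag, so near-empty windows can neither
create peaks nor count toward an "all probes" hypomethylation decision.
Similarly `callHypomethylated()` returns `no_call` when the −1/0 kb window
holds fewer than 3 probes in either replicate, instead of a vacuous "yes"
over an empty probe set.

# Coordinate and tie conventions

* All text I/O is 0-based half-open; internally intervals ride in
  `GRanges` (1-based closed) and conversion happens once at the boundary.
* TSS-relative windows are half-open `[lo, hi)`, upstream negative, so
  `[−1000, 0)` and `[0, 1000)` partition `[−1000, 1000)` with no double
  counting; a probe whose midpoint sits exactly on the TSS belongs to the
  downstream window.
* A probe's position is its interval midpoint — the symmetric choice for
  tiling probes; for minus-strand genes relative position is
  `tss − midpoint`, making upstream negative on both strands, and a
  minus-strand window maps to the reflected genomic interval
  `[tss − hi, tss − lo)`.
* `D+` is evaluated just below each window value with strictly-less
  counts, which handles ties between window and background correctly; the
  exact route assumes continuous data and is conditional on the observed
  pattern when ties exist.
* In the classifier, `N` bases are excluded from all counts and from the
  effective window length, so assembly gaps cannot fabricate CpG-poor
  windows; windows over 10% `N` are flagged.  The window scan uses step
  1 by default (exhaustive; the 10-bp step is kept for CG-density
  profiling, where it is the plotting convention), and the trailing
  offset `L − 500` is always scanned.  Ties for the best window go to the
  smallest offset.  The CG-content threshold is strict (`> 0.30`) with an
  `cgStrict = FALSE` escape hatch, because "content above 0.30" reads as
  a strict inequality and the boundary case is decidable either way.
* Island merging (`countCgiAndClusters()`) fuses overlapping or touching
  qualifying windows into single islands; three or more islands in a
  region raise the CGI-cluster flag.  The original Takai–Jones
  shrink/extend refinements are intentionally *not* applied to HCP/LCP
  calling, which is specified as a plain window scan; merging appears
  only in island counting.

# The synthetic experiment

The generator is the package's ground-truth instrument, and its defaults
*are* the study conditions; they are not tuned per analysis.

**Geometry.** 50-bp probes every 100 bp across −15 kb to +5 kb per gene
(the design of the arrays this pipeline targets), genes laid out on
simulated chromosomes with 10-kb untiled gaps, strands alternating.  The
full tiled range is the default deliberately: promoter-proximal domains
occupy a small fraction of the tiled probes, exactly as on the real
array, and that dilution is what keeps the array background representative
of "genome average".  Shrinking the tiled range concentrates planted
domains in the background mixture and materially distorts the
hypomethylation statistic (the background fraction below a window's
minimum scales directly with domain prevalence among probes), so tests
scale the number of genes down, never the per-gene geometry.

**Truth model.** Per gene and stage, one of three states: *methylated*
(one +Δ domain, default Δ = 1.0 log2 units, placed upstream-only at
−900/−100, downstream-only at +100/+900, or astride the TSS at −400/+400),
*hypomethylated* (a −Δ domain spanning −1400/+400), or *genome-average*
(no domain).  Methylated fractions per stage default to the observed
methylated-promoter fractions through the mid-blastula transition (0.324
pre-MBT, 0.449 at MBT, 0.470 post-MBT) and are nested via a shared latent
uniform — methylation, once gained, is maintained, matching the observed
stage stability.  The hypomethylated fraction defaults to 0.41 and is
constant across stages.  Hypomethylated domains are planted as *negative*
log2-ratio domains because that is what hypomethylation means on a
centered MeDIP array — methylation levels below genome average; a
promoter that merely lacked a domain would sit at the array median and
could never make ten probes look confidently non-enriched in two
replicates at once.  The −1400/+400 extent covers the −1/0 kb call window
plus one half KS-window margin on each side, so edge probes' windows stay
inside the domain.

**Noise.** Probe ratios add `√ρ·σ` of noise shared between replicates and
`√(1−ρ)·σ` replicate-specific, defaults σ = 0.3 and ρ = 0.8; realized
probe-level replicate correlation then follows
`(v_signal + ρσ²)/(v_signal + σ²)`, which the test suite checks, and
per-promoter MaxSixty summaries correlate at ~0.99, comfortably in the
reproducibility range reported for real duplicate MeDIPs.

**Sequences.** Promoter sequences are drawn from first-order Markov
chains, because CpG depletion — the property that separates LCPs from
HCPs — is a dinucleotide property invisible to i.i.d. base sampling.
HCP-truth genes carry a planted 500-bp island (C = G = 0.3, CpG
unsuppressed; o/e ≥ 0.8 and CG ≥ 0.5, comfortably above the 0.65/0.30
thresholds) inside depleted flanks; LCP-truth genes are depleted
throughout (`P(G|C)` shrunk 5-fold; every window o/e ≤ 0.4).  Each
sequence is verified against the step-1 classifier and resampled on
violation, so planted classes are exact by construction — the classifier
tests are then genuine recovery tests, not tautologies.  The HCP
probability is raised to 0.8 for hypomethylated-truth genes (the observed
"nearly 80% of hypomethylated promoters are HCPs") and compensated
elsewhere to keep the 0.65 marginal.

**Cohorts, marks, expression.** Cohort labels are multinomial with the
observed cohort proportions (733/608/438/2990 for maternal-degraded /
maternal-zygotic / zygotic / undetected).  Histone-mark flags follow
per-mark logistic models on the methylation state — H3K4me3 planted
toward hypomethylated promoters, H3K9me3 toward methylated ones, H3K27me3
neutral — and the post-ZGA expression flag follows a logistic model with
cohort base rates plus per-mark and methylation-state terms.  Setting all
log-odds to zero yields an exact global null for calibrating the
integration statistics.

**Reproducibility.** Every `simulate*` function derives its RNG stream
deterministically from the master seed (plus a fixed per-stream offset
kept under 2³¹), so identical configurations reproduce sequences, probe
tables, truth tables and downstream report hashes byte for byte.

# What the simulations do and do not establish

Passing recovery tests on this generator shows the chain implements its
own model correctly at realistic signal-to-noise: planted domains of 1.0
log2 units over σ = 0.3 noise are recovered with recall ≥ 0.95 (methylation)
and ≥ 0.90 (hypomethylation) at false-positive rates ≤ 0.05 and ≤ 0.02.
The generator does not emulate dye bias, spatial artifacts,
whole-genome-amplification bias, copy-number structure, probe
cross-hybridisation, or fragment-size effects, and planted domains have
sharp edges where real methylation boundaries are ragged.  Results on
real arrays therefore inherit all the usual MeDIP caveats; what the tests
certify is the correctness of the computation, not the chemistry.

# Statistical conventions

Fisher's exact test is two-sided with the probability-mass extremity
criterion (the `stats::fisher.test()` convention), with a one-sided flag
for users who want directional tests; the reported odds ratio is the
sample odds ratio, with Haldane's 0.5 added and flagged only when a cell
is zero.  The Yates-corrected chi-square is
`Σ (|O − E| − 0.5)² / E` with the correction capped at `|O − E|`.  No
multiple-testing correction is applied by default — the analysis reports
raw per-test p-values against fixed thresholds, and users who scan many
hypotheses can apply `p.adjust` downstream.  In the three-stratum
integration tables, "no_me" means *neither* statistically methylated nor
hypomethylated; genes carrying both flags at once (possible when a
downstream peak coexists with a confidently unenriched upstream window)
are dropped from strata with a warning rather than silently assigned.

# Problem sizes in the shipped tests

The test suite validates operations against brute-force oracles at sizes
chosen to exercise every code path while keeping the default run fast:
KS exactness by full enumeration at n ≤ 10, permutation agreement at
m ∈ {5, 8} vs n = 50, peak-caller equivalence on 10,000 random profiles,
classifier equivalence on 1,000 random 1-kb sequences, and end-to-end
recovery on 1,000-gene experiments at the default geometry.  These sizes
are the package's validation design; all of them are re-run by
`scripts/acceptance.R` from scratch under a caller-supplied seed.
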