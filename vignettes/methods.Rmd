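---
title: "Methods: somatic CNV mosaicism from FISH counts and single-cell profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic CNV mosaicism from FISH counts and single-cell profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`mosaicnv` quantifies somatic copy-number mosaicism in brain tissue from two
complementary assays and provides everything needed to validate the analysis
on synthetic data with known ground truth:

1. **FISH counting statistics** — mosaicism fractions (% of cells with a
   unique SNCA gain) with exact binomial intervals, and the 2×2 association
   machinery (Fisher exact, Yates chi-square, relative risk and odds ratio
   with confidence intervals, Spearman correlation, Mann–Whitney group
   comparisons with Bonferroni correction).
2. **A single-cell whole-genome CNV caller** — binned read counts →
   normalisation → segmentation → integer-ploidy fitting → QC gating →
   three-Gaussian mixture copy-number thresholds → rule-based call
   filtering — followed by clonality detection, gain/loss composition,
   inclusion association, gene overlap annotation and boundary-feature
   enrichment.

The pipeline starts at aligned-read intervals (BED) or per-bin count
matrices; read trimming, alignment and deduplication are out of scope, as
are gene-ontology enrichment services and exome/SNP-array analyses.

# The FISH mosaicism model

Each scored cell shows a number of signals for the SNCA probe and a
reference probe. A *unique gain* is more than 2 SNCA signals with exactly 2
reference signals. Cells with fewer than 2 signals of either probe, or more
than 2 of both, are excluded from the denominator: partial nuclei produced
by sectioning lose signals, and doubled nuclei duplicate them, so these
patterns are unscorable artefacts rather than evidence of loss or
aneuploidy. The mosaicism level of a sample is `100 * gains / analysed`,
reported to 2 decimals, with a Clopper–Pearson interval.

Association of gains (or CNVs generally) with α-synuclein inclusions uses
the 2×2 layout `a,b` (CNV+ with/without inclusion), `c,d` (CNV− ditto):

* relative risk `RR = (a/(a+b)) / (c/(c+d))`, Katz log-method interval
  `exp(log RR ± 1.96·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`;
* odds ratio `OR = ad/bc`, Woolf log-method interval;
* two-sided Fisher exact p by probability-mass ordering (the sum of
  hypergeometric probabilities not exceeding the observed table's, with a
  relative tolerance of 1e-7, the convention of mainstream statistical
  software);
* for very large tables, chi-square with the clamped Yates correction.

The Katz RR interval reproduces the printed interval of the bundled
Lewy-body NM+ table (2.52–14.43) exactly at 2 decimals. Odds-ratio
intervals are reported but not treated as a reproduction target: different
mainstream packages default to different OR interval methods and the Woolf
bound can differ from a printed value in the second decimal.

## Two statistics worth a note

* `spearman_corr()` computes the exact permutation p-value by full
  enumeration of all `n!` rank orderings for `n ≤ 10` (ties handled with
  midranks; enumeration is chunked so `10! = 3.6M` permutations stay within
  memory), and the t-approximation above that.
* `group_compare()` is the two-sided Mann–Whitney U with midranks (exact
  null for small untied samples), with the stated Bonferroni factor applied
  and capped at 1.

# The single-cell caller

## Coordinates and binning

All coordinates are 0-based half-open (BED convention); 1-based inputs must
be converted at the boundary. The genome is tiled into fixed-width bins
(default 250 kb — the resolution at which megabase-scale events are
detectable with under a million reads); a read contributes to the bin
containing its start coordinate, strand ignored. The Y chromosome is binned
but never called.

## Normalisation and segmentation

Counts are divided by bin width (so the shortened last bin of each
chromosome is not depressed) and scaled so the autosomal mean is exactly 1.

Segmentation is recursive binary segmentation with the
circular-binary-segmentation statistic: within a chromosome, the candidate
sub-segment maximising the two-sample t statistic between the segment and
the rest is accepted when a permutation test on that scan statistic gives
p < 0.01 (1000 permutations, seeded), and recursion continues into the
three resulting parts. The segment-versus-rest form matters: a prefix/suffix
split statistic dilutes a short interior event into a long flank and loses
it (measured: a 5–10-bin event on a ~260-bin chromosome reaches only
|t| ≈ 2.9 against a null 99th percentile ≈ 3.7). The scan is exhaustive
over all (start, length) pairs up to 60 bins and uses a ~25%-spaced length
grid with every start above that, followed by a local exhaustive boundary
refinement; the permutation test always uses the unrefined scan maximum so
observed and null statistics are comparable. Permutations stop early as
soon as the exceedance count makes rejection certain — the decision is
unchanged, flat chromosomes just exit cheaply.

## Ploidy

The integer scale is fitted by grid search over `c ∈ [1.5, 6]` (step 0.05)
minimising `Σ (c·m_i − round(c·m_i))²` over autosomal bins, where `m_i` is
the segment mean of bin i; ties go to the smaller multiplier. Segment means
rather than raw bins enter the sum, because per-bin amplification noise
would otherwise dominate the objective. A featureless diploid profile
scales to 2 (the smallest exact multiplier), and a tetraploid cell is
identified as such only when some event (e.g. a lost chromosome at 3:4
relative depth) anchors the scale — a genuinely featureless tetraploid is
indistinguishable from a diploid, which is the well-known limitation of
coverage-only ploidy estimation.

## Quality control

Three gates, all configurable:

* total reads **> 800,000** — below this, 250-kb bins are too shallow for
  confident megabase-scale calls;
* **MAPD < 0.3** — the median absolute difference between consecutive bins
  of the ploidy-scaled profile (within chromosomes, autosomes only), a
  local noise measure insensitive to genuine copy-number structure;
* **confidence ≥ 0.8** — the fraction of autosomal bins whose segment mean
  copy number lies within 0.25 of its nearest integer. The cited
  confidence score is defined verbally (how well the data conform to
  integer copy-number states); this fraction-of-genome formulation
  preserves the meaning of the 0.8 threshold and is the package's own
  formula.

MAPD is computed on linear copy-number values; a log2 variant is a
configuration switch away but the linear scale is the default because the
thresholds it is compared against are quoted on that scale.

## The mixture filter

Copy numbers of all called segments across a batch are pooled (unweighted
by segment length) and fitted with a three-component Gaussian mixture, EM
initialised at means (1, 2, 3), free variances, convergence at a
log-likelihood change below 1e-8 or 500 iterations, five seeded restarts.
Cutoffs invert a cumulative two-tailed probability of 1% of the component
nearest 2: `μ₂ ± Φ⁻¹(0.995)·σ₂`. With μ₂ = 2 and σ₂ = 0.55/Φ⁻¹(0.995) this
yields the canonical (1.45, 2.55) pair; cutoffs are symmetric about μ₂ by
construction. Degenerate fits (a collapsed component, or too few segments)
fall back to the median and MAD of the values in [1.6, 2.4].

One calibration guard applies when cutoffs are derived inside
`call_cells()`: σ₂ is floored at the sampling noise of the smallest allowed
call — the within-segment per-bin residual sd divided by √3 (three bins
being the minimum call size). On clean batches the pooled segment means
cluster so tightly around 2 that the fitted σ₂ can drop to ~0.02, and a
±0.05 cutoff band would turn every fluctuation into a call; no cutoff
tighter than minimal-call noise can separate events from noise, so the
floor is the narrowest defensible band. On data with realistic
amplification noise the fitted σ₂ (~0.2) exceeds the floor and the guard
is inactive.

## Call filtering

Three removal rules, each leaving a reason code:

* **(a) size** — calls spanning fewer than 3 bins;
* **(b) wave** — calls that look like a smooth coverage undulation rather
  than a sharp step. Each boundary's flank (the 3 nearest outside bins,
  summarised by their median so a one-bin boundary error cannot poison the
  estimate, clamped at zero so an opposite-phase dip cannot cancel an
  elevated shoulder) is compared with the cell's baseline; if subtracting
  the mean flank excess moves the call toward baseline by more than
  `max(0.15, 0.25·|call excess|)`, the call is removed. The thresholds were
  calibrated on simulations of AR(1) log-normal amplification waves
  (correlation 0.95): at moderate amplitude (stationary sd 0.2) 88–92% of
  ripple-induced ≥3-bin calls are removed while ≥98% of sharp planted
  events survive. Stronger genome-wide waves defeat any local shape rule,
  but such cells drift whole chromosomes off integer states and fail the
  confidence gate before reaching the filter. An earlier design —
  re-estimating the call mean at doubled bin size over its own interval —
  is a no-op (the mean of the same counts over the same interval is
  invariant to re-binning), which is why the flank-referenced form is used;
* **(c) recurrent borderline pericentromeric** — calls within 0.2 of a
  cutoff, overlapping a pericentromeric zone (centromere ± 2 Mb), and
  recurring at an overlapping locus in ≥ 3 cells. The borderline width,
  pad and recurrence count are configurable; none is prescribed by the
  filtering convention this rule automates, so they are explicit knobs.

Calls spanning an entire chromosome at uniform integer copy number are
classified *pure aneusomy*; cells with fitted ploidy ≥ 3.5 are labelled
*polyploid*; both are excluded from CNV composition tallies.

# Downstream analytics

* **Clonality**: single-linkage grouping of same-kind calls whose left and
  right boundaries each differ by ≤ 1 Mb (the tolerance is a parameter);
  groups must span ≥ 2 cells, and members may differ in copy number, since
  a clone can legitimately be called at 3 in one cell and 4 in another.
* **Composition**: gains/losses per cell type with the gain fraction at one
  decimal and a Fisher comparison between types.
* **Sizes**: Mann–Whitney on Mb sizes, medians to 2 decimals.
* **Inclusion association**: per-stratum 2×2 tables via `build_table2()`
  and the full `risk_ratios()` output.
* **Boundary enrichment**: a 1 Mb window centred on each call boundary
  (clipped windows flagged); the observed base-pair overlap with a feature
  track is converted to a z-score against one shared set of 3000 random
  1 Mb regions per run (chromosomes chosen proportional to eligible space,
  uniform start); z > 1.96 is enriched, z < −1.96 depleted. Base-pair
  overlap is the default statistic; element count is the obvious
  alternative reading and can be computed from the same tracks. Per-call
  aggregation reports both per-boundary status and calls enriched at both
  boundaries, with paralogous segmental-duplication pairs listed when the
  track carries pairing information.

# The synthetic-data generator

The generator defines the conditions every recovery and calibration test
runs under; its defaults are the study conditions the package is designed
around, and they are not tuned per test.

* **Genome**: 20 autosomes (70 down to 25 Mb, 950 Mb total) plus a 40 Mb X
  and 10 Mb Y — exactly 4000 bins at 250 kb. Centromeres sit at 40% of
  each chromosome (2 Mb). A named SNCA locus lives on chr4 so
  locus-aware association tests can run. Feature tracks: telomeres
  (terminal 1 Mb of each end — a stand-in definition, chosen because the
  catalogue the real analysis used does not define one), fragile sites,
  and segmental duplications placed in paralogous pairs, including pairs
  planted to flank "hotspot" loci so that SD-mediated CNVs can be
  simulated with both boundaries inside a pair.
* **Cells**: integer copy-number ground truth (baseline ploidy 2, or 4 for
  tetraploid cells; non-overlapping events; whole-chromosome aneusomies),
  then counts `~ Poisson(depth_share · CN/ploidy · exp(g))` with `g` an
  AR(1) Gaussian field (stationary sd `amp_sd`, coefficient `amp_corr`)
  restarted at chromosome boundaries, and optional per-bin dropout.
  `amp_sd` reproduces MAPD-style local noise; `amp_corr` near 1 produces
  the low-frequency waves of uneven whole-genome amplification. The AR(1)
  form is a modelling choice — real wave artefacts are not quantified
  anywhere — chosen because it gives two interpretable knobs. Read
  depth defaults to 1e6 (≈250 reads per bin); downsampling is binomial
  thinning, which is distributionally exact for counts.
* **Cohorts**: per-type cell counts with per-type gain probabilities
  (defaults 0.45 for neurons, 0.95 for non-neurons — the composition the
  assay observes), ~30% of cells carrying 1–3 sub-chromosomal events of
  log-normal size (median ≈ 5.5 Mb), a few percent tetraploid or
  aneusomic, an SNCA-gain carrier probability, and inclusion status drawn
  at 0.33 for carriers versus 0.08 for others (target relative risk ≈ 4.1).
  Clones are planted by copying one event into k cells with bounded
  boundary jitter. Decoy (non-clonal) calls used in clone-recovery studies
  are drawn with a minimum pairwise boundary separation of 2.5 Mb: ground
  truth can only label a call non-clonal if it does not satisfy the
  clonality criterion with respect to any other call, so the separation is
  what makes the label coherent rather than a tuning knob.
* **FISH counts**: per cell, true SNCA copies 3 with probability π else 2,
  reference always 2; a whole probe drops out with probability d
  (independent of gain state — a sectioned or poorly hybridised nucleus
  loses the probe entirely), and a spurious extra signal appears with
  probability s. The analysability rule then removes affected cells from
  the denominator without biasing the estimator, which is the property the
  exclusion rule exists to protect.

What the generator does **not** emulate: GC-content and mappability bias
(hook present, off by default), sequence-level reads, imaging artefacts
beyond the two probe artefact rates, and real segmental-duplication
sequence homology. Passing recovery tests therefore demonstrate the
pipeline's statistical behaviour under the stated noise model, not
performance on any particular sequencing platform.

# Reproducibility and problem sizes

Every stochastic function takes a `seed`; `run_pipeline()` fans one global
seed out to per-stage child seeds (a deterministic hash of seed and stage
label), so stages are individually reproducible and a full run is
byte-identical under the same configuration. The test-suite and acceptance
studies use: 50 cells × 4000 bins for event recovery, 2000 windows × 3000
random regions for enrichment calibration, 50 seeded replicates for clone
recovery, 300 replicates for risk-ratio interval coverage, and a 30-cell
demo run for the end-to-end check — sizes chosen so the full suite runs on
a laptop in minutes while leaving Monte-Carlo margins well clear of the
thresholds being checked.

# Known limitations

* Sub-megabase events (fewer than ~4 bins at 250 kb) are below the
  caller's design resolution, mirroring the assay it models.
* Ploidy is unidentifiable for featureless polyploid cells (see above).
* The wave filter is a local shape heuristic standing in for manual
  multi-resolution review; wave-like artefacts with sharp edges are
  indistinguishable from real events by construction.
* The confidence-score formula is the package's own concretisation of a
  verbal definition; only the 0.8 threshold's intent is preserved.
* FISH simulation models unique gains only — losses and aneusomies are
  unscorable under the analysability rule, exactly as in the assay.
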