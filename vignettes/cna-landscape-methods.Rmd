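---
title: "Methods: copy-number landscape analysis of segmented tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number landscape analysis of segmented tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnascape)
```

# Scope and data model

`cnascape` analyzes cohorts of segmented somatic copy-number profiles — the
tab-delimited SEG tables produced by circular-binary-segmentation pipelines
on SNP/aCGH arrays — through five stages: gain/loss state calling,
genome-wide frequency and arm-level profiling, breakpoint extraction with a
permutation hotspot test, chromothripsis-like pattern scanning, and Ward
clustering of cohort copy-number matrices. Raw-array normalization and the
segmentation itself are upstream of this package; its atomic input is a
segment `(sample, chromosome, start, end, log2 ratio)`.

Internally all coordinates are 0-based half-open; the SEG dialect on disk
(1-based inclusive) is converted on read. The coordinate frame is a
`genome_build`: chromosome lengths, p/q arm intervals and centromeres
derived from a UCSC-style cytoband file (arms from `p*`/`q*` band names,
centromere as the union of `acen` bands), plus a configurable telomere
width, 10 kb per chromosome end by default, following the UCSC gap-track
convention — the literature using these filters never defines "telomere"
precisely, so the width is an explicit parameter rather than a constant.
Sex chromosomes are excluded from the default analysis set to avoid
gender-composition bias in mixed cohorts. A three-chromosome 300-Mb toy
build ships for fast simulation and testing; a condensed hg19 autosome
table (lengths and centromeres, the only genome features any stage needs)
ships for realistic bin counts.

# Calling and profiling

Segments are called **gain** when `log2 > 0.2` and **loss** when
`log2 < -0.2`, with strict inequalities so that boundary values remain
neutral. These cutoffs are the standard thresholds for one-copy changes in
impure tumor material on log-ratio arrays; both are parameters.

The genome is tiled with 1-Mb bins (final partial bin retained, so bin
length enters rate-based statistics correctly). Per sample and bin, a
state must cover **more than half of the bin** and beat the opposite state
to be assigned; ties give neutral. This majority rule is a design choice —
how per-segment calls become per-bin states is rarely stated in the
cohort-profiling literature — and it guarantees one state per sample-bin,
hence `gain_freq + loss_freq <= 1` in the frequency profile. The test
suite pins the rule to a per-kilobase brute-force majority count.

An **arm-level event** is a single CNA covering more than 50% (strict) of
a chromosome arm. Because segmentation splits single biological events,
maximal runs of consecutive same-state segments are merged before the 50%
test; the literal single-segment reading is available via
`merge_adjacent = FALSE`. Arm gain and loss frequencies (fraction of
samples carrying an event per arm) are correlated across arms with
Pearson's r; tumor cohorts characteristically show negative correlation —
chromosome arms tend to be recurrently gained or recurrently lost, rarely
both.

# Breakpoints and hotspots

A **breakpoint** is the boundary between two adjacent retained segments
whose log2 values differ by strictly more than 0.4, after removing
segments smaller than 10 kb; boundaries falling in telomeres or
centromeres are ignored, as array behaviour there is dominated by probe
sparsity and repeat content. The filter order is fixed (size filter,
adjacency, delta threshold, exclusion zones) and pinned to a brute-force
oracle. When retained segments do not abut, the breakpoint is placed at
the midpoint of the gap.

Breakpoints are counted on the 1-Mb grid and compared with a permutation
null: each of 10,000 permutations relocates every breakpoint to a uniform
random allowed position on its own chromosome, preserving per-sample,
per-chromosome totals. The per-bin p-value is the upper tail of a
**Poisson law with the permutation-estimated null mean**, then
Bonferroni-corrected (x number of bins) and thresholded at 0.01. The
parametric tail is the package's most consequential numerical choice: the
smallest raw empirical p at 10,000 permutations is 1e-4, which can never
clear a Bonferroni correction over ~2,800 genome-wide bins, so a smoothed
tail is required for the test to be able to reject at all; `"normal"` and
`"empirical"` alternatives are provided. When a bin's null mean is zero
but breakpoints were observed, the Poisson mean is floored at `1/n_perm`.
Hotspot bins are annotated for >= 1 bp overlap with user-supplied region
sets (common fragile sites and non-fragile contrast regions); the package
bundles small synthetic illustrative BEDs, not any published CFS list.

# Chromothripsis-like patterns

The scan works at array-signal level: a chromosome region qualifies when
it shows at least 20 **copy-number status switches** — consecutive
retained (>= 10 kb) segments that change call state *and* jump by at least
0.4 in log2 (note `>=`, versus the strict `>` of breakpoint extraction;
the two filters are stated with different inequalities in the parameter
conventions this package follows) — and a **clustering likelihood ratio**
of at least 10 on the log10 scale. The LR compares a Poisson model with
rate `k/L` inside the candidate region against a homogeneous rate `N/G`
on the chromosome:

$$\log_{10} LR = \frac{k \ln(\lambda_1/\lambda_0) - (\lambda_1 - \lambda_0) L}{\ln 10},
\qquad \lambda_1 = k/L,\; \lambda_0 = N/G.$$

It is zero under homogeneity, strictly increasing in `k` for enriched
regions, and is pinned to an independent evaluation of the two Poisson
log-likelihoods at 1e-9. The scan slides windows of every width from 30 Mb
(the minimum affected-region size reported for this phenomenon on arrays)
up to the chromosome, in 5-Mb steps; qualifying windows are merged,
trimmed to the span of their switches (re-expanded to 30 Mb when
narrower), and re-evaluated once. A sample is a chromothripsis-like case
when any chromosome qualifies; per-chromosome "pulverization" shares use
positive samples as denominator.

Two consequences of this LR deserve note. First, a whole-chromosome event
has `k = N` and `L = G`, making the LR zero — chromosome-wide
pulverization is invisible to a same-chromosome homogeneity contrast; only
sub-chromosomal clustering can be detected. Second, the LR scales as
`k (ln r - 1 + 1/r)/ln 10` with `r = G/L` when the rest of the chromosome
is quiet, so a qualifying region needs **many tight oscillations**: ~22
switches spread over 40 Mb of a 120-Mb chromosome only reach a log10 LR of
about 4 and can never pass the threshold of 10. The simulator's defaults
(80 oscillations of 0.25–0.3 Mb fragments, amplitude 0.6) were therefore
chosen analytically to sit inside the detectable regime on all toy
chromosomes (expected LR 12–22), not tuned empirically. Passing detection
tests consequently show that the scan finds dense oscillation patterns; they
do not show sensitivity to sparser, borderline patterns, which this
statistic genuinely cannot reach.

# Clustering

The cohort matrix is bins x samples. The default encoding is the called
state (+1/0/-1), which is robust to platform signal-scale differences when
cohorts mix array types; a length-weighted mean-log2 mode is available.
Samples are clustered on Euclidean distance with Ward linkage (`hclust`
method `ward.D2`, the Ward criterion on unsquared Euclidean distances) and
cut into k = 2 major clusters by default; sub-cluster structure is left to
the user via the returned tree. Cluster-versus-rest clinical enrichment
uses two-sided Fisher exact tests with unknown labels excluded from
denominators.

# The synthetic cohort generator

Every statistical stage is exercised against `simulate_cohort()`, which is
first-class, seeded and deterministic (integer coordinates; log2 noise
from R's default RNG stream). Per sample and chromosome, boundaries come
from a Poisson process (exponential segment lengths, mean 2 Mb) and
segment means are `N(0, noise_sd)` plus the amplitudes of planted events:

* **arm events** with per-arm *exclusive* gain-or-loss propensities
  (0.3–0.5 by default), amplitude 0.4, covering 60–95% of the arm — this
  exclusivity is what induces the negative arm gain/loss correlation;
* **focal events**, Poisson-distributed per sample (mean 6), log-uniform
  sizes 100 kb–10 Mb, amplitude +/-0.6 — at toy-genome scale this breakpoint
  budget matches the per-Mb breakpoint rates of large SNP-array cohorts;
* **chromothripsis-like chromosomes** in 6% of samples (the incidence
  reported for head-and-neck tumors), parameters as motivated above;
* an **HPV-like subgroup** (14% of samples, matching the HPV-positive
  share of large head-and-neck cohorts) carrying a forced 3q gain, never a
  3p loss, with its own clinical site and HPV-positivity rate;
* optionally a **breakpoint hotspot bin**, boosted to a target rate
  multiple by injecting 25-kb spike segments with 0.6 jumps on both sides.

The uniform-null preset (`sim_null_config()`) carries no events and raises
segment-mean noise to sd 0.18, so adjacent-segment jumps exceed 0.4 at a
rate giving ~17 breakpoints per 300-Mb sample — the per-genome rate of
~138 breakpoints per ~2.9-Gb sample scaled down — with uniform positions,
which is the null under which hotspot type-I error is measured. The
two-group preset (`sim_two_group_config()`) plants a coherent high-burden
arm-level background (propensities 0.7–0.8) against the quiet 3q-gain
subgroup, the structure used to benchmark clustering recovery (adjusted
Rand index against planted labels) and label enrichment.

What the generator deliberately does **not** model: tumor purity and
subclonality, allele-specific copy number, probe-level noise and
re-segmentation artifacts, platform batch effects, and correlated
biological structure beyond the planted events. Passing tests therefore
demonstrate correctness of the statistics under the stated generative
model, not performance on real arrays; on real data the breakpoint null,
in particular, inherits whatever positional biases survive segmentation.

# Numerical and procedural choices

* Threshold boundaries: call cutoffs and the breakpoint delta are strict
  (`>`); the status-switch jump is `>=`; the arm-event fraction is strict
  (`> 0.5`). Boundary cases are tested explicitly.
* Ties in the bin-state rule resolve to neutral; ties in arm-event runs
  resolve to the largest run per state, at most one gain and one loss
  event per sample-arm.
* Segments with missing log2 are dropped with a warning, never imputed.
* All randomness (simulation, permutation) flows through explicit seeds;
  seeded runs are byte-identical, which the suite checks at file level.
* Problem sizes in the test-suite and acceptance script — 100-sample null
  cohorts, 200-sample recovery cohorts, 1,000 permutations, 100 seeded
  replicates, 20 clustering seeds — were chosen as the smallest cohorts at
  which the binomial error of the measured rates is clearly below the
  acceptance margins.

# Known limitations

* The clustering LR cannot flag whole-chromosome pulverization (see
  above), and its exact correspondence to web-server implementations of
  chromothripsis-like scanning is unknown; the statistic is isolated
  behind `clustering_lr()` so an alternative can be swapped in.
* Whether published hotspot analyses shuffled breakpoints or whole CNA
  intervals is ambiguous; this package shuffles breakpoint positions,
  the simpler reading, and keeps the choice local to
  `permute_breakpoints()`.
* Arm-level frequencies treat acrocentric p-arms like any other arm if the
  cytoband file defines them; cohort summaries on builds without
  acrocentric p-arm annotations will simply skip them.
* The bundled CFS/NFR files are synthetic illustrations; real analyses
  should supply published region lists as BED.
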