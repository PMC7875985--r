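---
title: "Testing GWAS risk-variant enrichment in open chromatin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing GWAS risk-variant enrichment in open chromatin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ocrenrich)
```

## The scientific question

Most genome-wide significant risk variants for complex diseases fall in
non-coding DNA, and each association signal drags along a haplotype of
variants in high linkage disequilibrium (LD), any of which could be causal.
One productive way to interpret such signals is to ask whether they are
*concentrated* in a functional annotation — here, open chromatin regions
(OCRs) mapped by ATAC-seq in specific cell types — and, one level deeper,
in the subset of OCRs that carry a particular transcription-factor binding
motif. A positive answer nominates the cell type as a mediator of genetic
risk and the transcription factor family as a candidate regulatory network.

`ocrenrich` implements this analysis end-to-end: LD-proxy expansion of
index variants into risk loci, two *independent* enrichment statistics, de
novo motif discovery and scanning, motif-based peak subsetting, and a
dual-test significance rule. Because the headline numbers of any real
analysis depend on large external data sets (reference LD panels,
brain ATAC-seq atlases, GWAS catalogues), the package also ships a
first-class synthetic-data generator that plants a known enrichment effect,
so every stage can be validated against ground truth without downloads.

## The unit of counting: risk loci

A *risk locus* is an index variant plus its LD proxies — all panel variants
on the same chromosome within a 1 Mb window whose `r² > 0.8` with the index
(strict inequality; `r² = D²/(pA qA pB qB)` computed from phased
haplotypes). A locus *overlaps* an annotation when the index or any proxy
falls inside an annotation interval. All coordinates are BED conventions:
0-based, half-open, chromosome names compared as opaque strings. Interval
sets are normalized (sorted; overlapping or bookended intervals merged)
before any overlap arithmetic, and the Jaccard statistic between two sets
is intersection bases over union bases (0 for two empty sets, so pairwise
matrices stay total).

## Two enrichment statistics

The package deliberately implements two nulls with different failure modes
and only reports an annotation as enriched when **both** adjusted p-values
fall below α = 0.05 (the dual-test rule).

**Locus-shift permutation test.** The observed statistic is the proportion
of loci overlapping the annotation. For the null, the annotation intervals
inside each locus window are circularly shifted by one shared uniform
offset per locus per permutation (wrapping at the window edges),
independently across loci; this preserves the local annotation density and
spacing while breaking the variant–annotation alignment. The shift window
is the locus span extended on each side by the larger of 50 kb and the
longest annotation interval intersecting the span, which guarantees that
every overlapping interval can also shift fully off the variants — without
the extension a locus covered by one long interval would have a degenerate,
shift-invariant null. The permutation p-value uses the add-one estimator
`(1 + k)/(1 + N)` with ties counting toward rejection, so it is never 0 and
errs conservative. Implementation note: for each locus the set of offsets
under which some variant is covered is itself a union of integer intervals,
so the test samples offsets and tests membership instead of physically
shifting interval lists; the sampled distribution is identical and the
test also offers an exhaustive single-locus mode that enumerates all
offsets exactly.

**Matched-control test.** The observed statistic is the count `S` of
overlapping loci. Each index variant is matched to control variants from a
pool (all remaining panel variants) that share its bin triple on three
covariates — number of LD proxies, minor allele frequency, and distance to
the nearest transcription start site — excluding the index itself and any
pool variant in LD (`r² > 0.8`) with it. Each locus contributes a null
probability `p_i`: the fraction of its matched controls whose own locus
overlaps the annotation, floored at `1/(n+1)` and capped at `n/(n+1)` for
`n` controls so no locus is deemed impossible or certain. The p-value is
the exact upper tail `P(X ≥ S)` of the Poisson-binomial distribution of
`Σ Bernoulli(p_i)`, computed by dynamic-programming convolution — exact at
small locus counts where a normal approximation would misbehave.

Default matching bins: LD-proxy count `{0–1, 2–5, 6–10, 11–25, 26–50,
>50}` (the first bin includes 0 because an index can have no proxies at
all), MAF bins of width 0.05, and gene-distance bins `{<1 kb, 1–10 kb,
10–100 kb, 100 kb–1 Mb, ≥1 Mb}`. These are configurable; the published
tools this mirrors do not expose their exact internal bins. The default
minimum of 500 controls per index presumes a genome-wide pool; synthetic
studies use a scale-matched minimum (below).

**Multiple testing.** Within each stage the Bonferroni factor is the
number of tests actually performed in that stage — the number of
annotation sets in stage 1, the number of motif subsets tested in stage 3
— never a hard-coded constant. An optional sensitivity rerun excludes
loci whose index variant lies in the extended MHC region (chr6
26–34 Mb, half-open, judged on the index position only), where unusually
long LD distorts locus structure.

## Motif machinery

**Scanning with exact p-values.** Motifs are position weight matrices
(PWMs); match scores are log-odds in bits against an order-0 background
estimated from the scanned sequences. The null score distribution is
computed *exactly* by dynamic programming over motif positions on a score
scale discretized at 0.01 bits, and every window (both orientations) whose
exact p-value is ≤ 1e-4 is reported. Windows containing `N` are skipped.
The order-0 background keeps the DP exact and simple; a higher-order
Markov background is a possible extension but changes the DP state space.
An 8 bp exact-match word has `p ≈ (1/4)^8 ≈ 1.5e-5`, under the 1e-4
threshold, while a 6 bp word (`(1/4)^6 ≈ 2.4e-4`) cannot pass it — short
motifs genuinely yield no reportable occurrences at this threshold, and
the subsetting stage records them as excluded rather than erroring.

**De novo discovery.** A discriminative k-mer search over widths 6–8:
every literal k-mer present in the target sequences (counting each
sequence once, zero-or-one occurrence per sequence; a pattern and its
reverse complement are one candidate) is tested against background
sequences with a one-sided Fisher exact test, and the E-value multiplies
the p-value by the number of candidate patterns evaluated across all
widths in the run. Candidates with `E ≤ 0.05` are ranked and greedily
deduplicated (Hamming distance ≤ 1 at equal width, either orientation).
This is a deliberate simplification of regular-expression-refinement
discoverers: no wildcard refinement, no EM, no GC-matched background
weighting beyond the user-supplied background collection. It is not meant
to match any specific tool's output, only to find strongly planted or
strongly enriched literal words — which is what the downstream subsetting
consumes.

**Known-motif matching.** Discovered motifs are compared to a PWM library
by the best ungapped alignment over all offsets and both orientations,
scored as the mean per-column Pearson correlation over at least 4
overlapping columns. Ties (common for repetitive motifs) break toward the
longer overlap, then the smaller offset. This is a similarity surrogate
without alignment p-values; the match threshold (default 0.6) is
deliberately permissive because mean-Pearson saturates quickly for sharp
matrices.

**Peak subsetting.** `subset(m)` contains the peaks with at least one
occurrence of motif `m` fully inside the peak; `noMotif` contains the
peaks in no subset and serves as a negative-control annotation. Motifs are
excluded, and logged with the applied rule, when they have no occurrences,
when they lack a known match (where required), or when their subset falls
below the minimum size.

## The synthetic study and what it does (not) emulate

`synthetic_config()` fixes the study conditions; all defaults were chosen
once, at design time, to mirror a desk-scale version of a real analysis:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 2 Mb, i.i.d., GC 0.41 | human genomic GC; large enough for ~4 % peak coverage |
| focus peaks | 500, length 300 ± 60 bp (≥100) | ATAC-seq-like peak geometry |
| planted motif | `GCAGCTGC` (E-box core with context) in 30 % of peaks | 8 bp so exact matches pass the 1e-4 scan threshold |
| decoy annotations | 3 peak sets, placed off the focus peaks | negative-control annotations unlinked to the effect |
| haplotype panel | 200 haplotypes × 2000 variants; 20 kb blocks, 2–4 founders, mutation 0.02, MAF ≥ 0.05 | block-structured LD with a realistic MAF floor |
| risk loci | 60 index variants; effect = fraction forced to overlap the target subset | comparable order to a large GWAS top-hit list |
| negative controls | 2 variant sets of 60, effect 0 | unrelated-trait GWAS stand-ins |
| matching | default bins; `min_controls` 10 | a 2000-variant pool cannot yield 500 controls per bin; 10 keeps the floor `1/(n+1)` ≤ 0.09 |
| `min_subset` in workflows | 25 | scale-matched to 1000 out of 76 145 peaks at full scale |

The generator plants enrichment at the index-placement level: a fraction
`effect` of index variants is drawn conditional on their locus overlapping
the motif-bearing peak subset, the rest unconditionally. It does not
simulate association statistics, coalescent-accurate LD, repeat structure,
or realistic peak-length distributions; passing tests therefore demonstrate
the statistical machinery and its calibration under idealized geometry, not
robustness to genomic confounders such as GC bias or clustered annotations.
Index variants are drawn only from pool variants for which matched-control
selection actually succeeds, and draws are repaired (still under the seed)
if removing the chosen indices from the pool starves a bin — the
matched-control test treats missing controls as an error by design, so the
generator guarantees testability; the conditioning applies identically to
effect, non-effect and control draws, preserving calibration.

## Numerical and degenerate-input choices

* Jaccard of two empty sets is 0, not `NaN`; bookended intervals merge.
* `r²` requires polymorphic variants; monomorphic input is an error, not 0.
* A variant on a chromosome with no TSS gets gene distance `+Inf`
  (it lands in the last distance bin).
* Score discretization is 0.01 bits; the DP and the scanner share the same
  rounding, so exact-distribution p-values are exact for the discretized
  score, and the test suite verifies them against full word enumeration up
  to width 8.
* Permutation p-values use add-one smoothing; Poisson-binomial tails are
  exact; ties count toward rejection everywhere.
* All randomness flows through explicit integer seeds; identical seeds
  give byte-identical fixtures and reports.

## Calibration and power at the study conditions

With `effect = 0`, both tests' type-I error at α = 0.05, measured over 200
independently regenerated fixtures (panel, peaks, genes and loci; 1000
permutations each) against the 500-peak focus annotation, lies within the
binomial 95 % band around 0.05 (the suite asserts exactly this).
Regenerating the fixture per replicate matters: a single fixture's
realized variant–peak overlap rate is itself one random draw, so
replicates conditioned on it have a systematically shifted rejection rate.
Both tests run slightly conservative (median null p ≈ 0.6): the
locus-shift null is discrete at 60 loci, and the matched-control floor
`1/(n+1)` is non-negligible at tens of controls.
Against much smaller annotations (e.g. the ~150-peak motif subset) the
discreteness bites harder and both tests become distinctly conservative —
a real limitation at desk scale that disappears as annotation size, locus
count and control count grow. With `effect = 0.5`, both tests reject for
the target annotation, and the full workflow flags the planted-motif
subset while flagging neither negative-control variant set, in ≥90 % of
seeded replicates (asserted over 20 replicates at 1000 permutations; the
problem sizes here are the package's chosen study conditions).

## Known limitations

* The locus-shift window rule (span + max(50 kb, longest intersecting
  interval)) is one reasonable operationalization of "shuffle within the
  locus"; published tools do not document their exact boundary rule, and
  p-values are not expected to be numerically identical to them.
* One haplotype panel serves both enrichment tests; a real analysis might
  use different LD references for each, which can make their proxy sets
  disagree.
* The k-mer discoverer cannot represent degenerate positions inside
  candidates (beyond reverse-complement collapsing), so motifs whose
  information content is spread across many weak positions are found only
  via their strongest literal word.
* Mean-Pearson motif similarity has no significance calibration; treat
  match scores as rankings, not evidence.
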