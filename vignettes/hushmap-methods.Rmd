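---
title: "Methods: classifying and profiling HUSH chromatin targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and profiling HUSH chromatin targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hushmap)
```

## Scope and model

The human silencing hub (HUSH: MPP8, TASOR, PPHLN1) deposits H3K9me3 via
SETDB1 at transposons and transgenes, but a large fraction of its binding
sites carry no H3K9me3 and instead coincide with sites of RNA polymerase II
accumulation, particularly transcription termination sites (TTS). `hushmap`
implements the downstream genomics of this biology as a reusable pipeline:

1. **Region consolidation.** Peak calls from several factors/marks (MPP8,
   TASOR, H3K9me3, ...) are merged into one non-redundant region superset by
   one-dimensional mean shift on peak midpoints.
2. **H3K9me3 enrichment calling.** Tag counts in the superset regions are
   compared between an H3K9me3 IP group and a control group with a
   negative-binomial Wald test.
3. **Classification.** Regions overlapping MPP8 peaks split into
   `HUSH_K9POS` (TASOR overlap + H3K9me3 call), `HUSH_K9NEG` (TASOR
   overlap, no call) and `MPP8_ONLY` (no TASOR); everything else is
   `UNCLASSIFIED`. Regions are oriented by the ratio of plus- to
   minus-strand PRO-seq tags around their centers.
4. **Profiling.** Depth-scaled coverage heatmaps, aggregate profiles with
   bootstrap bands, differential and unit-scaled maps, a centroid-shift
   statistic, a transcriptional readthrough index, repeat/trinucleotide/TTS
   annotation enrichment, and length- and transcription-normalized CLIP
   RT-stop enrichment.
5. **Synthetic data.** A generator that plants the three classes with known
   signal structure and perturbation effects, so every stage is testable
   with ground truth and no downloads.

Coordinates are 0-based half-open (BED convention) throughout. Tags are
single-base positions: the 5' end of a read on its own strand, or the
RT-stop base for CLIP.

## Region consolidation by mean shift

Peak midpoints are clustered per chromosome with a flat (boxcar) kernel of
half-width `bandwidth` (default 500 bp): each midpoint moves to the mean of
all midpoints within the bandwidth of its current position until the step
is below `tol` (default $10^{-3}$ bp) or 200 iterations. Points converging
to the same mode (within 0.5 bp; with a flat kernel members of one basin
reach an identical fixed point, so this tolerance is generous) form one
region whose extent is the span of its member peaks; overlapping spans are
merged so the superset is non-overlapping and every input peak lies in
exactly one region. All three knobs are exposed; the defaults reflect
typical ChIP peak spacing at a few hundred bp resolution.

## H3K9me3 enrichment test

`compute_size_factors()` implements median-of-ratios normalization (the
median across all-positive regions of each sample's ratio to the row
geometric mean, rescaled to geometric mean 1). `nb_enrichment_test()` then
models normalized counts as negative binomial. Per-region dispersions are
estimated by method of moments, $\hat\alpha = (s^2 - \mu)/\mu^2$ from the
pooled within-group variance, and averaged within count-abundance quantile
bins of at least ~100 regions; bin means (not medians) are used because
the moment estimator is unbiased in the mean while its sampling
distribution is right-skewed. Two guards keep the extreme tail honest —
which matters because BH across thousands of regions rejects on p-values
of order $\alpha/n$: each bin's dispersion is floored at the global mean
(so downward bin noise, and the selection of apparently clean bins, cannot
tighten the test), and two standard errors of the bin estimate are added
to propagate the estimation uncertainty that a plug-in Wald variance
ignores. Both corrections are negligible when dispersion is well
determined and cost little power (a 64-vs-4 contrast among hundreds of
null regions is still called at $q \ll 0.05$). The Wald statistic uses
$\mathrm{Var}(\log \hat\mu_g) \approx (1/n_g)(1/\mu_g + \alpha)$ per group;
$\log_2$ fold change is $\log_2(\mu_{IP}/\mu_{ctrl})$ with 0.5 added to
both means only when one is zero (so a 64-vs-4 contrast is exactly 4).
P-values are BH-adjusted across all regions jointly; a region is called
enriched when $q \le \alpha$ (default 0.05) **and** $\log_2 FC \ge$
`lfc_min` (default 1).

One practical caveat drove a pipeline-level choice: over a consolidated
superset, a large fraction of regions is genuinely enriched in the IP, so
median-of-ratios factors absorb part of the enrichment and bias fold
changes toward zero. `classify_pipeline()` therefore normalizes by total
aligned tags (rescaled to geometric mean 1) — the same per-million logic
used for track scaling — while `compute_size_factors()` remains the
default for expression-style tables where most features are unchanged.

## Interval-overlap odds ratio

`fisher_overlap()` fixes an explicit "available genomic slots" 2x2
convention: n11 = overlapping (A,B) pairs, n12/n21 = non-overlapping A/B
intervals, and n22 = $\max(0, \lfloor G/(\bar L_A + \bar L_B)\rfloor - n11
- n12 - n21)$ empty slots, where $G$ is the genome size and $\bar L$ the
mean interval length. The odds ratio is the sample odds ratio with 0 and
$+\infty$ conventions for zero cells (an optional Haldane 0.5 correction is
available for plotting); the p-value is the two-sided Fisher exact test.
Inputs must be merged and are treated as unstranded; this is checked as a
precondition rather than fixed silently. The construction is validated
against a brute-force oracle that builds the table by direct pairwise
sweeps.

## Heatmaps, profiles, and bootstrap bands

`build_heatmap()` tabulates tags by signed distance from each region center
into bins of `bin_size` bp over $\pm$`half_width` (defaults 50 bp and 5 kb,
matching the $\pm$kb axes typical of this literature; both are exposed
because real analyses vary them). For minus-strand regions the distance
sign is flipped, so the positive axis is always the sense direction. Values
are scaled by $10^6/\text{total aligned}$. Bins whose genomic footprint
leaves the chromosome are stored as `NA` and excluded from aggregates
rather than zero-filled, avoiding edge-artifact dilution. Two exact
invariants are tested: the unscaled matrix mass equals the number of tags
in the windows, and doubling the library total halves every value.

`aggregate_profile()` averages (or takes medians of) rows;
`per_billion_per_base_per_region` divides raw per-bin counts by
(regions x bin width) and scales by $10^9/\text{total}$, the
reads-per-billion-per-base-per-region unit used for meta-feature profiles.
`bootstrap_band()` resamples rows with replacement `n_boot` times (default
1000) and reports the 0.025/0.975 quantiles per bin; resampling indices are
drawn once from the supplied seed, so bands are reproducible.
`unit_scale()` affinely maps a profile to span [0, 1] to compare shapes
across conditions of different amplitude; constant profiles are an error
because they have no shape.

## Shift and readthrough statistics

Knockout of the termination factor WDR82 both weakens HUSH ChIP signal and
displaces it downstream, with readthrough transcription past affected
terminators. Two scalar statistics quantify this:

* `centroid_shift(wt, ko)` is the difference of signal-weighted mean
  positions. Each profile's baseline — estimated as the mean of the
  outermost 25% of bins per side — is subtracted first so that flat
  background does not dilute the centroid toward zero, and the weighted
  mean can be restricted to a central `signal_window` (the package's
  analyses use $\pm 2$ kb inside $\pm 5$ kb windows) to keep far-flank
  noise, whose contribution grows with $x^2$, out of the estimate. Weights
  are not clipped at zero, which keeps the estimator unbiased.
* `readthrough_index()` is $(d + 1)/(b + 1)$ with $d$ the sense tags in
  (TTS, TTS + 2 kb] and $b$ the sense tags in the 2-kb body window ending
  at the TTS; the pseudocount keeps empty windows finite. Effects are
  reported as KO/WT ratios per terminator.

## CLIP RT-stop enrichment

Stops are assigned to the highest-priority same-strand feature containing
them; counts always partition the total. Enrichment per category $f$ is
$$E_f = \frac{S_f/S_{tot}}{(L_f/L_{tot}) \cdot (T_f/\bar T)},$$ with $L_f$
the union length of the category, $T_f$ its sense PRO-seq density, and
$\bar T$ the length-weighted mean density, plus one pseudocount tag on stop
and PRO counts. This doubly-normalized form has the fixed point $E_f = 1$
when stops fall proportionally to $L_f T_f$, which makes the null testable;
a simpler raw form $S_f/(L_f T_f)$ is available behind a flag.

## Annotation content

`presence_matrix()` renders binary repeat-presence maps with the same
geometry as signal heatmaps. `class_category_enrichment()` compares
per-region overlap indicators between two classes with Fisher tests per
category (sample odds ratio; degenerate all-or-none tables are reported as
OR 1, p 1) and BH correction across categories. Trinucleotide densities
use overlapping windows (count/(length - 2), pooled per class; N bases
void their windows; minus-strand regions are reverse-complemented).
`feature_overlap_fraction()` reports the fraction of regions within
`slop` of a feature category; the TTS analyses use slop 500 bp, a
deliberate, reported choice since an exact overlap rule for "at a
terminator" is not standardized.

## The synthetic dataset

`synthetic_config()` defaults define the study conditions: a 10 Mb
two-chromosome genome; 100 `HUSH_K9POS`, 200 `HUSH_K9NEG` and 100
`MPP8_ONLY` regions with log-normal widths (median 1 kb, clamped to
300-2000 bp) and at least 11 kb between regions so default heatmap windows
never overlap; per-bp tags drawn NB with background 0.01/bp and dispersion
0.2 (per-bp means are small, so region totals are near-Poisson);
enrichment folds MPP8 8x everywhere, TASOR 8x at HUSH classes only,
H3K9me3 10x at `HUSH_K9POS` and `MPP8_ONLY`; RNA high (10x) at
`HUSH_K9NEG` and low (2x) at `HUSH_K9POS`; 75% of `HUSH_K9NEG` regions
placed with a gene TTS at their center; A-rich sequence (p(A) = 0.5) at
`HUSH_K9POS`; L1-like repeats at `HUSH_K9POS` and LTR-like repeats at
`MPP8_ONLY`. Perturbations: WDR82-KO retains 20% of HUSH ChIP signal,
shifts it +500 bp downstream at the terminator-proximal `HUSH_K9NEG`
subset, and adds 5x readthrough in the 2 kb past those terminators;
MPP8 depletion multiplies RNA by 4 at `HUSH_K9POS` and 0.5 at
`HUSH_K9NEG`. PRO-seq signal follows gene bodies on the sense strand
(10x); at terminator-proximal regions the region-level PRO signal models
RNAPII accumulating up to the TTS and is therefore planted on the upstream
side only — a symmetric boxcar would spill engaged-polymerase signal past
the terminator and make the readthrough index insensitive by construction.
Peak files are emitted from the truth table because peak calling is out of
scope here.

What the generator does **not** emulate: read-length and fragment-size
effects, mappability and blacklist structure, copy-number variation,
realistic repeat sequence, correlated replicates, or peak-caller
idiosyncrasies. Passing recovery tests on this generator therefore
demonstrates that the statistics measure what they claim under known truth
— not that any particular biological dataset will reproduce the original
study's numbers.

## Validation suite and problem sizes

The acceptance checks (mirrored in `scripts/acceptance.R`) use: 500 random
interval-set pairs against the brute-force overlap oracle; class recovery
on 10 simulated datasets of 400 regions; null FDR of the NB test on 10
draws of 2000 regions (mean 100, dispersion 0.1); bootstrap coverage on 20
replicates of 200 iid Normal(3, 1) rows; the CLIP fixed point with $10^5$
stops over five features; KO effect recovery over 8 simulated datasets
(median centroid shift, median readthrough ratio, and RNA differential
sign rates on 5 of them); and the planted 0.75 terminator fraction with
slop 500. These sizes were chosen so each block completes in the minutes
range on one core while leaving Monte-Carlo noise well inside the test
margins (e.g. the per-dataset centroid-shift SD is ~40 bp, so the
median over 8 datasets sits within one 50-bp bin of truth with high
probability).

## Known limitations

* The NB Wald test is asymptotic; with one replicate per group it falls
  back to cross-group variance for dispersion and is conservative.
* `fisher_overlap` fixes one defensible null (mean-length slots); other
  slot conventions change n22 and hence the absolute odds ratio, though
  rankings are stable.
* The mean-shift consolidation treats peaks as points (midpoints); very
  wide, asymmetric peaks can merge with neighbors their summits would not.
* Orientation by PRO-seq strand ratio is undefined at truly bidirectional
  loci; the deterministic '+' tie-break keeps output reproducible.
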