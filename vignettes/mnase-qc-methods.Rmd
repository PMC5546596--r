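---
title: "Methods: MNase-seq quality control with mnaseqc"
author: "mnaseqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MNase-seq quality control with mnaseqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnaseqc)
```

## The problem

MNase-seq profiles nucleosome organization genome-wide: micrococcal
nuclease digests the chromatin, the protected ~147-bp nucleosomal DNA is
sequenced, and the read pile-ups reveal nucleosome occupancy (how often a
position is covered) and positioning (how consistently a nucleosome sits
at the same coordinate across cells). Unlike ChIP-seq or DNase-seq, the
signal is not enriched anywhere in particular, so conventional
peak-calling QC does not apply. `mnaseqc` implements a set of QC scores
that are specific to the MNase-seq assay, plus a caller for
well-positioned nucleosome arrays that gives the data a ChIP-peak-like
unit of analysis.

## From reads to profiles

Reads below MAPQ 30 are removed (BED input carries no MAPQ and bypasses
the filter, with a logged message). Reads are then turned into canonical
nucleosome footprints:

* single-end: the read is extended to 147 bp in its 3' direction from
  the 5' end;
* paired-end: the fragment is replaced by the 147-bp window centered on
  the fragment center (73 bp on each side; the extra base is placed
  downstream so that the middle 73 bp is symmetric around the center).

Two genome-wide signals are built from the footprints. The **occupancy
profile** accumulates the middle 73 bp of each footprint (center ± 36 bp);
the **center profile** counts footprint centers per bp. Mass clipped at
chromosome edges is tracked so that occupancy mass + clipped mass equals
73 × the footprint count exactly. Internally the package uses
GenomicRanges/IRanges containers (1-based, closed); all BED and bedGraph
output is converted at the boundary and printed 0-based half-open, so
files round-trip bit-exactly.

## Sample-level QC scores

**Sequencing coverage** is `n_reads × 194 / G`, where 194 bp is the
nucleosomal + linker repeat length, `n_reads` counts mappable post-filter
reads (single-end) or fragments (paired-end), and `G` is the effective
genome size: 2.7e9 bp for hg19/hg38, 1.87e9 bp for mm9/mm10. Custom
genomes must supply `G` explicitly; the package deliberately does not
estimate it from the FASTA.

**Rotational score.** Nucleosomal DNA shows a ~10-bp periodicity of
AA/TT/AT dinucleotides, reflecting the rotational setting of the helix on
the histone octamer. For every footprint the genomic 147-mer is read 5'→3'
on the read's strand (reverse-complemented for minus-strand reads, since
the periodicity is defined relative to the nucleosome entry site), and for
each position p in 4..143 the fraction of footprints with AA/TT/AT at
(p, p+1) is recorded. The 140-point curve is mean-centered and its
discrete Fourier power spectrum taken; the rotational score is the power
at the bin nearest 0.1 cycles/bp (bin 14 of 140, exactly the 10-bp
period) divided by the total power of the positive-frequency half
spectrum. This normalization makes the score unitless in [0, 1], invariant
to affine rescaling of the curve, and a pure 10-bp cosine scores exactly
1. Scores above 0.08 pass. Reads are capped at 10 million by uniform
downsampling before this computation.

**Nucleosomal DNA length.** For paired-end data the template-length
distribution is used directly. For single-end data the estimator is the
start-to-end distance: after deduplication (key: chromosome, 5' position,
strand) and the 10-million cap, every plus-strand 5' end is paired with
all minus-strand 5' ends within 250 bp downstream on the same chromosome,
and the distances are histogrammed. In both modes the estimate is the
distribution mode (ties resolved toward 147 bp, then toward the smaller
length, for determinism); estimates in 140–155 bp pass. Shorter estimates
indicate over-digestion, longer ones partial digestion.

## Promoter profiles and scores

Occupancy is binned at 10-bp resolution over TSS windows (−1 kb..+2 kb by
default; custom regions use center ± 1 kb). Minus-strand rows are
column-reversed so columns always run in the direction of transcription,
and rows are sorted by within-window signal for the heatmap. The column
means form the aggregate curve, which is smoothed with a normalized
Gaussian kernel (default sd 3 bins = 30 bp — wide enough to suppress
single-bin noise, narrow enough to resolve a ~194-bp repeat). Kernel
weights are renormalized at the curve ends, so a constant curve is left
unchanged.

Landmarks on the smoothed curve: scanning rightward from the TSS, the
first strict local maximum is the +1 nucleosome; scanning leftward, the
first strict local minimum is the NFR and the first maximum beyond it the
−1 nucleosome. Plateaus take their leftmost bin. The **NFR score** is
(mean(S₊₁, S₋₁) − S_NFR) / (max S − min S) over the 3-kb window; the mean
(rather than the sum) keeps the score within [−1, 1] and is the default
(`numerator = "sum"` is available). Scores ≥ 0.4 pass. The **positioning
score** is the coefficient of variation — population (n-denominator)
standard deviation over mean — of the three spacings between the +1..+4
nucleosome peaks; scores ≤ 0.4 pass, and fewer than four downstream peaks
is reported as a Fail with a reason rather than an error.

## Well-positioned nucleosome arrays

The center profile is smoothed with a Gaussian of window ± 73 bp and sd
30 bp; the absolute difference between adjacent bp forms the modified
profile; positions that are maximal within ± 73 bp (and positive) are
marked, ties keeping only the leftmost position of a tying window; and
adjacent marked maxima are connected by linear interpolation (held flat
beyond the outermost maxima) to give the dense nuc-array curve. Note that
with sd 30 the kernel is not negligible at the ± 73 bp window edge
(~5% of its peak), so for an isolated center spike the strongest
modified-profile features are the truncation steps at ± 73–74 bp; this is
a property of the published parameters, not an artifact of this
implementation. Local maxima are taken on the absolute-difference profile
as defined; `on_smoothed = TRUE` switches to the smoothed profile for
comparison.

The curve is divided by its genome-wide mean — computed over all
assayable bp of chromosomes present in the input header, not only
non-zero bp — giving fold enrichment over background with mean exactly 1.
Arrays are maximal runs strictly above 2-fold and strictly longer than
600 bp; each is reported with its mean fold value (BED5). Enrichment of
arrays over a region set (3-kb downstream promoters, union-DHS sites) is
the fraction of arrays overlapping the merged regions by ≥ 1 bp divided by
the fraction of the effective genome the regions cover; DHS folds above 2
pass. Gene-level annotation intersects arrays with TSS ± 3 kb promoters
and reports the summed overlap in bp, −1 when no array touches the
promoter (BED6). The downstream-promoter set (TSS..TSS+3 kb, strand-aware)
and the annotation promoters (TSS ± 3 kb) are deliberately two different
definitions, each used where stated.

## Synthetic data: what it emulates, and what it does not

The simulators define the study conditions for every test:

* `simulate_positioning_region()` — the coverage-resolution design: a
  1200-bp region, five potential nucleosome centers 194 bp apart, 1-bp
  reads marking centers, uniform ± 5 bp perturbation (the perturbation
  distribution is not further specified anywhere, so uniform over the
  integers −5..5 was chosen once and made configurable). Read counts per
  coverage fold use the region length in place of the effective genome
  size, so 1-fold means one 194-bp-repeat pass over the region. The
  positioning score for these regions is the mean of the *raw* nuc-array
  curve (fold normalization would cancel between two regions of the same
  dataset anyway).
* `simulate_periodic_genome()` — i.i.d. background with AA/TT/AT planted
  every `period` bp, planted after the background draw so the planted
  phase is exact. Reads only show the periodicity if their footprints are
  phase-locked to the planted comb (starts on the 10-bp grid), which is
  how the rotational fixtures place them — in real chromatin the
  periodicity is nucleosome-relative rather than genome-absolute, and
  phase-locked placement emulates that.
* `simulate_reads()` — fragments drawn from planted centers (Gaussian
  jitter = positioning strength) or uniform background, point-mass or
  discretized-normal fragment lengths, single-end or proper-pair output,
  SAM/BED writers and a JSON-lines truth record sufficient to recompute
  every planted quantity. The single-end length estimator only recovers
  the fragment length when plus- and minus-strand reads sample shared
  nucleosome positions, exactly as in real digests — fully random
  fragments carry no start-to-end signal, and the tests rely on planted
  centers for that reason.
* `simulate_barrier_fixture()` — 20 barrier sites on a 1-Mb chromosome,
  phased centers every 194 bp across 1.5 kb downstream of each site, half
  the reads phased (jitter sd 15 bp) and half uniform background: a
  realistic mid-coverage sample in which arrays should be called at the
  barriers. With `positioning_fraction = 0` it is the matched null.
* `simulate_promoter_curve()` — a parametric aggregate curve: baseline
  0.6, Gaussian crests (amplitude 0.4, sd 40 bp) at −215 bp and at
  +65 + k·194 bp, a trough of configurable depth at −50 bp, optional
  additive noise.

None of the simulators model MNase sequence bias beyond the planted
dinucleotides, fragile-nucleosome digestion kinetics, chromatin
heterogeneity between cell subpopulations, or mappability gaps. Passing
tests therefore demonstrate correctness of the computations and the
qualitative behavior of the scores, not performance on real tissue data.

## Numerical choices and edge cases

* Smoothing of per-bp signals uses zero-padding outside the chromosome
  (no signal beyond the ends); aggregate-curve smoothing renormalizes the
  kernel at the ends instead, because a promoter curve is a window into a
  larger signal, not a whole chromosome.
* Fragment center of an even-length interval is the floor of the
  midpoint; "middle 73 bp" is center ± 36 bp, the only symmetric reading
  of an odd width. Paired fragments are re-extended to 147 bp (not 146)
  for consistency with the single-end footprint; configurable.
* Histogram-mode ties resolve toward 147 bp; tied local maxima of the
  modified profile keep the leftmost position; spectral-bin ties cannot
  occur (a single bin is selected).
* Degenerate inputs warn and return well-defined values: constant
  dinucleotide curve → score 0/Fail; all-zero center profile → all-zero
  curve and no arrays; flat aggregate curve → no landmarks, both promoter
  scores Fail with a reason; zero detected arrays → enrichment fold
  undefined, judgment Fail.
* All randomness (downsampling, simulators) flows through explicit seeds
  and restores the caller's RNG state; two runs with the same
  configuration and seed produce byte-identical outputs.

## Known limitations

* The positioning score is computed on the kernel-smoothed aggregate,
  and smoothing imposes a typical spacing on the maxima of pure noise;
  a structureless (e.g. shuffled) profile therefore often still yields a
  *passing* positioning score, while its NFR score collapses. The two
  scores must be read together — the NFR score is the one that catches
  shuffled or NFR-less profiles.
* With the 10-bp binning of promoter windows, crest positions that are
  not multiples of the bin (e.g. a 194-bp repeat) quantize to neighboring
  bins, leaving a small floor on the positioning score (~0.03–0.05)
  even for perfectly regular arrays. The pass cutoff of 0.4 is an order
  of magnitude above this floor. For the same reason the noise response of
  the score is cleanest at bin-aligned spacings.
* The NFR score is contrast-normalized (divided by the curve range), so
  it measures the *shape* of the promoter profile, not its amplitude; a
  curve with regular downstream crests but no planted trough still scores
  high on the shallow inter-nucleosome saddle. Noise, not trough removal,
  is what degrades it.
* Sequence-free mode (no genome FASTA) cannot compute the rotational
  score; the report marks it "not computed" and everything else runs.
* Problem sizes used throughout the test-suite and the reproduction
  script — 100 kb–1 Mb chromosomes, 20–100 k reads, 10–50 replicate
  seeds — were chosen as the smallest sizes at which every score is far
  from its decision boundary; all results are computed at run time from
  these synthetic conditions.
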