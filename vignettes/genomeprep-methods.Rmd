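---
title: "Methods: preprocessing and QC for short-read genome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and QC for short-read genome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomeprep)
```

This vignette documents the models and procedures behind each stage of the
package, the parameters that matter, the numerical choices, and what the
simulation-based tests do and do not demonstrate about real data.

## Coordinates and formats

Every coordinate inside the package is 0-based half-open. VCF and SAM
(1-based) and GFF3 output are converted at the I/O boundary, so interval
arithmetic, mask membership and hint clustering all use one convention.
Phred qualities are offset-33 on disk; offset-64 data is out of scope.
The VCF reader handles a deliberate subset (CHROM, POS, REF, ALT, the five
hard-filter INFO annotations, one sample's GT) and keeps every other field
as opaque text so that supported records round-trip byte-identically. `N`
bases are legal in reads; k-mer windows containing `N` are skipped.

## Junction linker clipping

Mate-pair libraries built by circularisation leave a junction linker
inside reads that cross the junction. The scan is ungapped: the linker
(and by default its reverse complement) is slid across every offset of
the read, including partial overhangs at the read ends whose aligned span
is at least `min_core`. A candidate qualifies only if

* `matches / aligned_length >= min_identity` (default 0.8), and
* its longest run of consecutive matching bases is at least `min_core`
  (default 9 bp).

The continuous-core rule is the essential part. A long linker scored only
by total matching bases accumulates spurious partial hits on random
sequence; requiring an exact 9-bp core multiplies the per-offset false
hit rate by roughly $4^{-9}$ while read-through junctions, which contain
the linker verbatim, always carry one. The identity threshold itself is
not part of the core rule and is configurable; 0.8 is the conventional
operating point for ungapped junction scans. Gapped alignment is out of
scope: junction read-through produces substitution-style noise only.

Ties among equal-match candidates break to the leftmost read offset, then
to the `+` strand, making results deterministic. The core run is required
to lie inside the read (it is contained in the aligned span by
construction). Clipped reads are truncated to the bases before the
junction start; a kept prefix shorter than `min_keep` (default 25 bp, a
floor below which a read stops being informative for assembly or
scaffolding) flags the member so the pair can be demoted to single-end
output, keeping paired files at equal cardinality. Clipped pairs are not
reoriented — downstream conventions differ, so reorientation is left to
the consumer.

For 454-style mate pairs the read is instead split at the junction:
forward segment before it, reverse segment after it. Trailing bases of
the reverse segment below `trim_quality` (default Q20) are removed
*before* reverse-complementing — the low-quality tail is a sequencing
artifact of the original orientation — and the quality string is reversed
alongside.

Adapter contamination is handled by whole-read dropping, never trimming,
because assemblers that model raw read ends require unmodified input.
Stage 1 drops reads containing any exact adapter k-mer (default k = 11,
both strands): long-fragment contamination. Stage 2 drops reads with an
exact terminal adapter prefix/suffix of at least `min_terminal_match`
(default 8 bp): adapter running off a read end, too short for stage 1.

## k-mer spectrum and genome size

Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
complement; k defaults to 23) are counted in compiled code with a rolling
2-bit encoding; correctness is pinned to a plain dictionary counter in
the tests. The multiplicity histogram $f(m)$ is analysed descriptively,
by smoothed local extrema, not by mixture-model fitting — the intent is a
transparent profile (error tail, main peak, side peaks), and at the
coverages where this method is used the peaks are well separated:

* a centred moving average (window 5 bins) smooths $f$;
* the **error cutoff** is the first local minimum after $m = 1$; if the
  smoothed spectrum rises from the start there is no error component and
  the cutoff is 0; if it only falls, coverage is too shallow to separate
  errors from genomic k-mers and fitting stops with an error;
* the **main peak** is the smoothed argmax beyond the cutoff;
* **secondary peaks** are other smoothed local maxima within a relative
  tolerance (default 0.12) of 0.5×, 2× or 3× the main peak, classified as
  heterozygosity, duplication or triplication peaks. The 12% tolerance
  reflects how far such side peaks drift from their ideal ratios in real
  spectra while staying well clear of neighbouring classes.

The genome size estimate is
$\hat G = \sum_{m > \text{cutoff}} m\, f(m) \,/\, \hat\lambda$:
k-mer instances above the error cutoff divided by the k-mer coverage
depth. For the depth $\hat\lambda$ the integer peak position is too
coarse at moderate coverage (at $\lambda \approx 47$ one bin is a 2%
step), so $\hat\lambda$ is the count-weighted centroid of the unsmoothed
counts over $[0.5, 1.5] \times$ the peak position. That window is wide
enough that the right-skewed single-copy distribution is not truncated
asymmetrically (a ±25% window biases the centroid visibly low) and
narrow enough to exclude the 0.5× and 2× side peaks. For reads of length
$L$ at base coverage $C$, $\lambda \approx C\,(L - k + 1)/L$.

Multiplicities above a cap (default 10 000) are binned at the cap; the
total instance count is preserved exactly, so the estimator is unaffected
unless the main peak itself approaches the cap.

## Insert-size estimation

The insert is the outer distance `max(pos + len) − min(pos)` of the two
mates on a contig — the convention scaffolders consume. Four gates
precede estimation: both mates on one contig; the contig at least 3× the
*target* insert (pairs on short contigs are biased toward short,
artifactual inserts — long inserts simply cannot fit, so short contigs
systematically under-sample the right tail); the expected orientation
(FR by default, the orientation of junction-processed mate pairs;
tandem pairs are always rejected); and both mapping qualities at least
20. A single robust pass then drops inserts beyond 10 median absolute
deviations (normal-consistent MAD) from the median before computing mean
and sd — wide enough to keep the genuine distribution intact, tight
enough to shed residual chimeric pairs. PCR duplicates are not collapsed
here; in the intended workflow duplicates are marked downstream.

## Assembly statistics

N50/L50 follow the standard cumulative definition on descending lengths.
The final-filter cutoff (default 250 bp, the read length of the library
that built the contigs) is inclusive: a scaffold exactly at the cutoff is
kept. Cutoff tables recompute every metric on the subset of scaffolds at
least each cutoff long. Report percentages round half away from zero at
the printed precision — the convention that reproduces published
completeness and repeat-fraction tables on recomputation; `round()`'s
half-even rule does not. N counts are literal `N`/`n` bases.

## Variant hard filtering

The per-site thresholds are applied exactly as strict keep conditions
(SNPs: `QD > 2`, `FS < 20`, `MQ > 40`, `MQRankSum > −12.5`,
`ReadPosRankSum > −8`; indels: `QD > 2`, `FS < 20`,
`ReadPosRankSum > −20`). Two points deserve note. The `FS < 20` keep
rule is considerably tighter than the customary `FS > 60` *fail*
threshold; it is implemented as stated. The indel rule set omits the
mapping-quality annotations by design. A record lacking an annotation
passes that rule by default — rank-sum statistics are undefined at sites
without both alleles observed, and failing them would discard exactly the
confident homozygous calls — but this is configurable.

Repeat-mask subtraction tests only the variant's start position
(half-open), ignoring indel spans: simple, reproducible, and at worst
conservative by a few bp per indel. Heterozygous density divides het
counts by an **explicitly supplied** non-masked length, never one derived
silently, because published denominators are typically rounded (a
"138 Mbp" denominator printed alongside densities of 0.0235 and 0.0089
per kbp is only consistent with both at its unrounded value); making the
denominator an input keeps the arithmetic auditable. Densities round
half-up at 4 decimals, zygosity percentages at 2.

## Homology hints for gene prediction

Per query, hits are ranked by score; the best is `TOP`, the next up to
two are `SECONDARY`, the rest are dropped ("maximum three hits" is read
as three in total). Score ties break by longer summed segment length,
then leftmost target start, then contig id — an invented but fully
deterministic order. Each aligned CDS fragment is cut back on both sides
by an amount depending on evidence class and rank (protein top 3 bp,
protein secondary 9 bp, transcript top 0, transcript secondary 3 bp):
alignment edges are least reliable for weaker hits and for cross-species
protein alignments. The cuts are applied literally in bp on target
coordinates even though protein alignments step in codons; a config
switch rounds protein cuts up to codon multiples for users who prefer
that. Over-trimmed segments (below 1 bp) are dropped.

Truncated fragments are clustered by single linkage under *strict*
overlap (half-open abutment does not merge) within one
contig/strand/evidence class; classes are not merged across because
protein and transcript evidence feed the predictor as distinct sources.
Hints are written as GFF3 `CDSpart` features with predictor-style
`src`/`mult`/`pri` attributes. Finally the retention rule keeps a
predicted gene only if it both overlaps a hint and has a protein-database
hit (flags computed upstream and supplied as inputs).

## Synthetic data and what the tests show

Every input class has a seeded generator emitting data plus a truth
table: genomes (i.i.d. bases at a set GC, default 0.4, plant-like; an
optional contiguous duplicated fraction copied to a disjoint location),
reads (uniform starts, both strands, uniform substitution errors,
optional adapter read-through), mate pairs (truncated-normal inserts;
junction linkers planted as read-through at recorded positions — the
real failure mode — at a per-read rate), pair alignments (proper FR
pairs on one contig), and annotated variants (each annotation drawn on a
known side of its threshold, so pass/fail truth is exact). Generators
restore the caller's RNG state and are deterministic under their seed.

Test problem sizes are chosen to finish in seconds while leaving
estimators enough data: genome-size recovery uses a 200-kb genome at 60×
(within 2% error-free, 5% at 0.5% base error), duplication detection a
10% duplicated segment, junction clipping 1000 pairs at 30% planted
linker rate (recall and precision ≥ 0.99), insert-size recovery 1000
pairs at N(5000, 300²). Randomized oracle suites (N50, interval merge,
ranking, truncation, hard filter) run 500 instances each against
brute-force reimplementations.

The simulations deliberately omit several features of real data: biased
or position-dependent error profiles and quality scores, indel
sequencing errors, coverage bias with GC, PCR duplicates, repeat
structure beyond a single duplication, and real linker/adapter sequence
families. Passing tests therefore demonstrate algorithmic correctness
and calibration under clean assumptions, not end-to-end performance on a
real sequencing run; on real data the operating characteristics (e.g.
clipping precision at 0.8 identity, the error cutoff position) depend on
the library and should be inspected via the reported counters and
spectrum plots.

## Known limitations

* The linker scan is ungapped; junctions disrupted by indels are missed.
* Spectrum analysis is descriptive; it does not estimate a
  heterozygosity rate, only detects whether a heterozygous peak exists.
* SAM parsing expects plain text with `@SQ` headers and primary
  alignments; BAM should be decompressed externally.
* The VCF subset preserves unknown fields as opaque text but does not
  interpret multi-sample or multi-allelic records.
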