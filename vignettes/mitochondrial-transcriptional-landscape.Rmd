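---
title: "Methods: inferring a mitochondrial transcriptional landscape from stranded RNA-seq"
author: "mitoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring a mitochondrial transcriptional landscape from stranded RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscape)
```

# The analysis problem

Plant mitochondrial genomes are pervasively transcribed: essentially every
position of both strands carries some RNA, at depths spanning several
orders of magnitude. Functional signals therefore live in the *shape* of
the strand-specific depth profile, not in presence/absence of reads:
transcription start sites (TSS) appear as sharp step-ups upstream of
genes, mature 3′ termini as drops after the stop codon, co-transcribed
gene clusters as continuously elevated depth across an intergenic gap, and
intron splicing as the balance between reads crossing spliced and
unspliced junctions. `mitoscape` operationalises each of these readouts
with explicit, tunable rules and validates all of them against a
synthetic-data generator with known ground truth.

# Data model and conventions

All coordinates inside the package are **1-based closed**, the native
convention of the IRanges/GenomicRanges containers the classes are built
on. Conversion happens only at I/O boundaries: GFF3 and the boundary TSV
are 1-based on disk, BED and bedGraph are 0-based half-open. Annotations
must be linearised; features spanning the origin of a circular genome are
not supported (split them at the origin before import).

Masked intervals (in practice: plastid-like insertions that attract
cross-mapping chloroplast reads) stay in the depth arrays, so coordinates
never shift, but are excluded from every statistic, and
`depthFromAlignments()` zeroes them so that a read overlapping a masked
interval contributes only its unmasked positions.

Per-base depth counts reference-consuming aligned bases (CIGAR M/=/X);
deletions do not increment depth. This fixes the conservation identity
used as a self-check: the sum of both depth arrays equals the aligned
bases of retained reads (before masking). Template-strand assignment
defaults to read 2 = sense, the TruSeq stranded chemistry used by the
libraries this analysis was designed around; `orientation = "read1-sense"`
covers the opposite chemistry. No mapping-quality filter is applied by
default (`min_mapq`), since the depth semantics should not silently
change with the aligner's quality model.

# Coverage statistics

`summarizeCoverage()` counts the two strands separately: the denominator
of every fraction is twice the unmasked genome length. This is the only
reading under which "fraction of the genome covered, considering both
strands" can be *smaller* than the single-strand fraction, and it is the
convention the package commits to. Intergenicity is strand-aware: a
position is intergenic on a strand when no exon of a same-strand gene
covers it, so antisense depth across a gene still counts as intergenic
signal on the opposite strand. The window histogram assigns each 100-bp
window (per strand) to the depth interval containing its mean, with
intervals half-open on the left — a window mean exactly at the lowest
break falls in the first bin.

# TSS inference from depth slopes

For each gene, `slopeProfile()` computes the least-squares slope of depth
against position in 50-bp windows across the 2-kb upstream region,
strand-aware and sign-oriented so that positive slopes mean depth rising
toward the gene. Least squares rather than an endpoint difference: on a
noiseless step the two agree, under Poisson noise the regression slope is
considerably more stable.

Windows are anchored at the gene-proximal end (the window adjacent to the
gene is always full) and placed every `stride` bp. The default
`stride = window` tiles the span without overlap. That tiling has a blind
spot: a depth step falling exactly on a tile boundary contributes nothing
to either adjacent within-window slope. With `stride = window / 2` every
possible step position is at least a quarter-window interior to some
window, which removes the blind spot at the cost of correlated neighbour
windows. The package therefore keeps the non-overlapping default (the
windows then satisfy the tiling invariant) and the recovery analyses in
the test suite run with `stride = 25`; on 100 simulated genes with
signal-to-background 5 and Poisson noise this recovers 100 % of true TSS
at rank 1 within 50 bp, versus ~95 % for the non-overlapping tiling.

`callTss()` ranks windows by slope (ties broken toward the gene) and
labels the top `top_n = 3` — multiple promoters per gene are the norm in
plant mitochondria, and with no published count of candidate sites per
gene the number reported is a parameter, as is an optional `slope_floor`.
A call is `matched` when a known TSS lies within `match_radius = 50` bp of
the window midpoint (a 100-bp total window); `inside_upstream_gene` when
the window overlaps another same-strand gene's exons (elevated depth there
says nothing about this gene's promoter); `upstream_of_known` when the
window lies 5′ of every known TSS — the signature of either an
unidentified promoter or a spurious genomic copy of a known promoter
sequence, which `scanPromoterSequences()` locates by exact matching on
both strands.

# 3′ termini

`callTerminus()` scans 50-bp windows downstream of the stop codon and
reports the first whose mean depth falls below `drop_fraction = 0.5` of
the gene-body mean. No numeric drop criterion is published for this kind
of analysis — the reported drops are visually unambiguous — so 0.5 is the
package's operationalisation, exposed as a parameter. When a same-strand
downstream gene's exons enter the scan before any drop, the call is
`obscured_by_downstream_gene` rather than forced into matched/unmatched.

# Co-transcription

Candidate pairs are same-strand genes ≤ 2 kb apart (nearest coding ends).
Pairs separated by < 150 bp, or overlapping, are excluded from
classification — their individual transcription bubbles overlap, so
continuity carries no information — but their depth statistics are still
reported for transparency. For evaluable pairs the minimum of 50-bp
windowed mean depths across the intergenic span is compared with
`tau = 0.5` times the weaker gene-body mean: at or above is `continuous`,
below is `drop`. The published classification was made by visual
continuity; on plateau-over-background geometry the evaluable pairs sit
far from τ = 0.5 on both sides (fixture ratios ≈ 0.99 vs. ≈ 0.1), so the
threshold choice is uncritical there, and raising τ can only convert
`continuous` calls to `drop` (monotonicity, tested). Only the ratio
criterion is applied — no absolute-depth floor — since the reference depth
is already the weaker gene's own mean.

# Splicing efficiency

For each intron, reads are counted that *cross* the exon/5′-intron
junction (EI5′) and the 3′-intron/exon junction (I3′E) on the unspliced
per-gene reference, and the exon–exon junction (EE) on the spliced
reference; a read crosses when its aligned span covers at least one base
on each side of the junction point. The 30-bp figure bounds the windows
in which junction evidence is evaluated, not a minimum overhang — a
minimum-overhang reading would discard most 89-bp reads asymmetrically.
Exon-only reads map to both references and cross no junction, so they are
excluded by construction. Counting is refused, with the reason reported,
when a flanking exon is shorter than the 30-bp window (the case of the two
trans-spliced nad5 introns around the very short exon 3).

The efficiency is

$$SE = \frac{N_{EE}}{N_{EE} + 0.5\,N_{EI5'} + 0.5\,N_{I3'E}}$$

The halving encodes molecule accounting: one unspliced precursor carries
*both* unspliced junctions, one spliced molecule carries a single EE
junction, so at equal per-junction sampling the unspliced molecule count
is half its junction-read total. SE/ratio tables are printed at two
decimals with half-up rounding. The I3′E/EI5′ ratio is reported as
undefined (empty cell), not infinity, when no EI5′ reads exist.

Group comparisons (cis vs. trans; branching vs. hydrolytic vs. both) use
standard one-way ANOVA via `stats::lm()`, with the degenerate
zero-within-variance case handled explicitly (`F = Inf`, `p = 0`; equal
group means give `F = 0`, `p = 1`).

# The synthetic world

`generateSynthetic()` emits what the analysis consumes — FASTA, GFF3, a
boundary TSV, a stranded bedGraph pair, and (via
`simulateJunctionReads()`) per-gene SAM files — rather than FASTQ, because
alignment is out of scope and direct emission keeps the tests hermetic.
Its stated world: background depth 20 on both strands (pervasive
transcription), gene plateaus drawn from 100–600 (signal-to-background
≥ 5, the regime where boundary inference is claimed to work), one step-up
per promoter with the gene-proximal promoter strongest, a terminus drop
100 bp past the gene end (standing in for tRNA-like processing sites),
per-base Poisson noise, and uniform random sequence with a 16-mer motif
planted at each primary TSS for the exact-match scan. Genes are spaced
> 2 kb apart unless a layout is given explicitly; `paperFixture()` supplies
the explicit layout whose 11 candidate pairs reproduce the published
geometry (3 continuous, 5 drop, 2 too-close, 1 overlapping).

Junction reads are generated at molecule level: of $n$ precursors,
$K \sim \mathrm{Binomial}(n, s)$ are spliced and yield one EE-crossing
read each; each unspliced precursor yields one EI5′- and one I3′E-crossing
read, with read starts uniform over the 30-bp window upstream of each
junction. Under this model the SE estimator equals $K/n$ exactly —
unbiased for the true splicing fraction $s$ with standard error
$\sqrt{s(1-s)/n}$ — which is what the parameter-recovery tests assert. A
plain "split $N$ reads binomially between the two references" scheme
would *not* recover $s$ (it converges to $2s/(1+s)$, because it ignores
that the unspliced form presents two junctions); the molecule-level
scheme is the one consistent with the estimator's own derivation. What
the generator does not emulate: fragment-length variation, sequencing
error, library-position biases, multi-mapping between recombined repeats,
and I3′E/EI5′ asymmetry from intron-half degradation kinetics (the
generator's two unspliced junctions are sampled symmetrically). A green
recovery test therefore establishes correctness of the inference rules on
clean step-shaped signal, not robustness to every artefact of real
libraries.

# Numerical and degenerate-input choices

* Fixed-precision output uses half-up rounding (`roundHalfUp()`), the
  convention of published SE tables; R's `round()` is half-even.
* Slope ties are broken toward the gene-proximal window; equal-slope flat
  profiles therefore return the windows nearest the gene, flagged
  unmatched.
* Zero total counts: RPKM and SE are errors (undefined normalisation),
  not zeros.
* The RPKM denominator is restricted to protein-coding genes
  (`proteinCodingIds()`); rRNA/tRNA depth would otherwise dominate a
  ribodepleted library's total.
* Read pairs count as one fragment by default (`count_mates = TRUE`
  switches to read counting); a read is counted for every per-gene
  reference it aligns to, matching multi-reporting alignment setups.
* Depth-based counting (when only a bedGraph is available) estimates
  fragments as exonic aligned bases / read length (default 89 bp) — an
  approximation, flagged as such in the documentation.

# Known limitations

Circular-origin features are unsupported (linearise first). TSS and
terminus calls inherit the resolution of the window size (± one window).
The co-transcription call is symmetric evidence — it cannot say which
promoter drives a continuous unit, nor distinguish genuine
co-transcription from an independent promoter buried in the upstream
gene's coding region; the `inside_upstream_gene` label marks where that
ambiguity applies. Splicing-mechanism labels are input metadata, never
inferred. The ANOVA treats per-intron SE values as independent
observations, as in the original analysis; introns of the same gene share
a precursor, so the test is descriptive rather than strictly inferential.
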