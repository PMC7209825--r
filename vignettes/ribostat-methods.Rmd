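---
title: "Methods and design of the ribostat Ribo-Seq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the ribostat Ribo-Seq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostat)
```

## The problem

Ribosome profiling (Ribo-Seq) sequences the ~26–34 nt mRNA fragments that a
translating ribosome protects from nuclease digestion, giving a
single-nucleotide-resolution map of translation. Primary processing of a
bacterial Ribo-Seq run involves a chain of small, convention-heavy steps:
trimming adapters and low-quality tails off single-end reads, turning
aligner output (SAM) into genomic intervals, flushing a rich NCBI GFF3 down
to CDS features, validating the library through the three-nucleotide
periodicity of metagene density around start codons, building normalized
genome-wide footprint profiles, counting footprints per gene
strand-specifically, and comparing translation levels between conditions.
`ribostat` implements this chain as one tested library plus a thin
command-line front end, exercisable entirely on synthetic data with known
ground truth.

## Coordinate conventions

All internal coordinates are 0-based half-open `[start, end)` — the BED
convention. GFF's 1-based closed convention appears only inside the GFF
reader and writer, which apply `start - 1` on input and `start + 1` on
output. In metagene coordinates, relative position 0 is the adenine of the
start codon (not +1); for a minus-strand CDS that adenine is genomic
position `end - 1`. A single internal convention with conversion at the
file boundary removes the usual off-by-one failure class, and the
conversion bijection is property-tested (500 random features round-trip
exactly).

## Read trimming

Trimming applies, in order: adapter clipping, sliding-window quality
truncation, and a minimum-length filter. The defaults mirror the standard
single-end invocation for this protocol: 2 seed mismatches, clip score
threshold 6, window 4 nt at mean quality 15, minimum length 12 nt,
Phred+33.

*Adapter clipping* scans every alignment offset of the adapter against the
read, left to right, including offsets where only an adapter prefix
overlaps the read's 3' end — read-through is the dominant contamination
mode when inserts (26–34 nt) are shorter than the 50-cycle read. A
candidate offset is seeded when the first `min(16, overlap)` bases contain
at most 2 mismatches, then scored with `+log10(4)` (≈ 0.602) per match and
`−Q/10` per mismatch, `Q` being the read base quality. The match increment
`log10(4)` is chosen so that the score-6 threshold is reached by exactly
ten perfect matches and not by nine (10 × 0.602 = 6.02; 9 × 0.602 = 5.42)
— the calibration point the tool family documents. The read is truncated
at the leftmost qualifying offset, removing the adapter and everything 3'
of it. Exact equivalence with any particular trimmer binary is not
promised; the calibration points above are.

*Sliding-window truncation* evaluates full-length windows from the 5' end
and truncates at the start of the first window whose mean quality drops
below the threshold. The comparison is strict: a window mean of exactly
15.0 passes. Only full windows are evaluated (a read shorter than one
window is judged by the mean of all its bases); evaluating partial
trailing windows was considered and rejected because it breaks the strict
boundary semantics above and makes trimming non-idempotent on its own
output.

*Length filter*: any 11-mer is expected by chance in a ~4.19 Mbp genome
(4^11 bases), so reads shorter than 12 nt cannot map specifically and are
dropped.

Invariants tested: outputs are prefixes of adapter-clipped inputs (bases
are never edited), `reads_in = reads_kept + reads_dropped`, idempotence on
quality-monotone output, and monotonicity in the quality threshold.

## SAM decompilation

Mapped records (flag 0x4 clear) are converted directly to BED6: `start =
POS − 1`, `end = start +` the CIGAR reference span (sum of M/D/N/=/X
lengths; I/S/H/P consume none), strand from flag 0x10, name from the read
id, score from MAPQ. Secondary (0x100) and supplementary (0x800)
alignments are dropped by default since counting assumes one interval per
read; a flag keeps them. Fully-clipped records (reference span 0) are
skipped with a warning and counted. Sorting is a stable radix sort on
(chrom, start, end, name) so permuted inputs and reruns give byte-identical
files. The span arithmetic is verified against an independent per-base
walk oracle on random CIGARs.

## Annotation flushing

`extract_cds()` is a pure type/attribute filter: keep column-3 `CDS`
lines, take `locus_tag` from the attributes (split on `;`, first `=`,
percent-decoding), convert coordinates. CDS lines without a locus_tag are
skipped with a warning and counted — the NCBI dialect guarantees the tag,
but custom annotations may not. Duplicated locus_tags (joined CDS
segments) keep the first occurrence, since downstream counting requires
unique gene keys. No biological filtering is done: pseudogene or partial
CDSs typed `CDS` are retained.

## Metagene density, periodicity, and the A-site

For each CDS and each end assignment (5'/3'), read ends on the CDS strand
are mapped to positions relative to the start-codon adenine (strand-aware:
`p − start` on plus, `(end − 1) − p` on minus) and accumulated over a
window, by default −50 to +100 nt. Sums are divided by the number of CDSs
("average ribosome density per CDS"); per-CDS read-count weighting is
deliberately not applied by default. A CDS shorter than the downstream
bound contributes only up to its own 3' end. Overlapping genes — common in
bacteria — are counted independently, so one read may contribute to two
windows. No read-length filter is applied by default; `read_len_range`
exposes one.

The periodicity statistic reports the fraction of density in each frame
(positions mod 3) and the lag-3 Pearson autocorrelation of the density
vector; a healthy library shows one dominant frame and a lag-3
autocorrelation exceeding neighbouring lags. Zero-variance shifts return
autocorrelation 0 rather than NA so that flat densities score as
unperiodic; an all-zero density is an error, not a score.

The ribosomal A-site is mapped a fixed offset — default 14 nt, a parameter
because the exact value varies with organism and nuclease protocol —
upstream of the footprint's 3' end along the read's own 5'→3' axis:
`end − 1 − offset` on plus, `start + offset` on minus. The mapping is
undefined (an error) for reads not longer than the offset.

Genome profiles count the selected read end per (chromosome, strand,
position). With a numeric normalization factor `N` the counts are scaled
by `N /` (total mapped reads in the input) — the count expected had `N`
reads been mapped, TPM-like; the denominator is all mapped reads, not
reads in CDSs. Totals are conserved exactly and tested to 10⁻⁶ relative
tolerance. Profiles are written as GFF point features (`start = end =
position + 1`, score to six decimals) loadable in genome browsers.

## Counting and differential translation

Counting follows strand-specific coverage semantics: a read counts toward
every same-strand CDS it overlaps by at least one base (Ribo-Seq libraries
made with small-RNA chemistry place reads on the gene strand; an
`same_strand = FALSE` option preserves the antisense reading for other
chemistries). A read spanning two overlapping genes is counted once per
gene — the behaviour of interval-overlap counters generally — which
double-counts such reads; this is documented rather than hidden.
`covered_bases` is the union of read overlaps with the feature. The
implementation is verified against an all-pairs brute-force oracle on
every randomized fixture.

Normalization uses the median-of-ratios estimator: per-gene geometric-mean
reference over genes with no zero count, per-sample median of
count/reference ratios. Factors are reported unscaled (two identical
samples get factors (1, 1); a sample with doubled counts against one
reference sample gets (1/√2, √2)). The estimator is cross-checked in the
test suite against an independent implementation; the tiny discrepancy
(≲ 10⁻⁵ relative) comes from interpolating the even-length median in ratio
space here versus log space there.

The differential statistic is intentionally simple and fully specified:
`baseMean` = mean normalized count over the two conditions' samples;
`log2FC = log2((meanB + 0.5)/(meanA + 0.5))` (the +0.5 pseudocount bounds
fold changes at zero counts); p-values from a Welch two-sample t-test on
`log2(normalized + 1)`; Benjamini–Hochberg adjustment across genes. This
deliberately replaces a negative-binomial GLM with dispersion shrinkage;
numerical agreement with such models is not claimed, only directional and
recovery properties, which the tests measure. One contrast table is
written per unordered condition pair — `choose(N, 2)` files named
`Contrast_<A>_vs_<B>.txt` in design-sheet order of first appearance.
Reproducibility diagnostics use `log2(normalized + 1)`: Euclidean sample
distances, complete-linkage clustering, and PCA of gene-centered values.

A note on power: with three replicates per condition, a Welch t-test has
at most ~4 degrees of freedom, so its smallest attainable p-values sit
near the Benjamini–Hochberg cutoff when 10% of genes are differential at
α = 0.05. Sensitivity therefore depends strongly on the biological
dispersion: the recovery test simulates tight replicates (dispersion 0.02)
and measures mean recall ≥ 0.5 at a false-discovery proportion ≤ 0.15
over 20 replicate simulations; at dispersion 0.1 the same design detects
almost nothing. Users with noisy replicates should prefer a
moderated-dispersion method — this package's contrast statistic documents
its limits instead of hiding them.

## The synthetic-data generator

The generator stands in for a real bacterial dataset and defines the test
conditions:

- **Genome/annotation**: uniform-random sequence; 150–600 nt CDSs
  (multiples of 3, ATG-initiated on their own strand) packed without
  overlap on alternating strands, 20–100 nt gaps, 50 nt end margins so
  footprints can overhang gene boundaries.
- **Footprints**: 5' ends drawn inside CDSs with frame probabilities
  `frame0_bias : 1 : 1` (default 4, a strong but realistic codon-frame
  signature); lengths uniform in 26–34 nt; optional stall positions
  multiply local occupancy to emulate initiation-site pileups.
- **Reads**: sequencing length fixed at 50 cycles so every insert reads
  through into the 3' adapter, exercising the clip path by construction;
  qualities decay linearly (default start 38, 0.6 per cycle, Gaussian
  jitter sd 3, floor 2) — a deliberately simplistic model.
- **Alignment is bypassed**: the generator emits the SAM an ideal aligner
  would produce (perfect matches, correct FLAG/CIGAR) plus the truth BED,
  so every downstream stage can be tested with or without the trimming
  front end. Re-implementing a read aligner is out of scope.
- **Count matrices**: log-normal gene means (meanlog log 100, sdlog 1),
  negative-binomial counts with `size = 1/dispersion` (default dispersion
  0.1), per-sample depth factors, and a known differential set (default
  10% of genes at 4-fold, half up, half down).

What passing tests on these data do **not** show: robustness to MNase
sequence bias, rRNA contamination, sequencing errors, multi-mapping, or
overlapping-gene read assignment — none of which the generator emulates.

## Determinism and problem sizes

Every generator is byte-deterministic under its seed, and the pipeline
itself is randomness-free, so reruns on identical inputs produce
byte-identical text outputs (tested). The test suite runs at deliberately
small scale — hundreds to a few thousand reads per simulated sample,
100-seed periodicity replicates at 2,000 reads over 10 genes, 500–2,000
gene count matrices — sizes at which every stochastic check has
comfortable margins while the whole suite stays fast on one CPU.

## Known limitations

- Text SAM only; BAM must be converted upstream (e.g. `samtools view`).
- One interval per read is assumed; multi-mapper handling is whatever the
  aligner left in the SAM (primary records only by default).
- The contrast statistic is underpowered at low replication and high
  dispersion, as quantified above.
- Stop-codon metagene profiles, pause-site calling and codon-level
  occupancy are out of scope; the metagene machinery is anchored on start
  codons.
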