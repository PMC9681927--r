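---
title: "Methods: ortholog-guided reconstruction and pseudogene scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog-guided reconstruction and pseudogene scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofill)
```

# The problem

De novo transcriptome assemblies of non-model plants are redundant and
fragmentary: one locus is typically represented by several overlapping
contigs, and genes of interest — floral regulators, meiotic genes — are
often present only in pieces. When a conserved ortholog from a reference
species is available, two questions become tractable: can the full-length
coding sequence be reconstructed from the fragments plus the raw reads,
and does the reconstructed sequence carry pseudogenization events
(frameshift indels, premature stops, retained introns) relative to the
ortholog? `orthofill` implements that workflow together with the
expression-side analyses that surround it (quantification, clustering,
replicate QC, differential expression) and a synthetic-data module that
generates every input with ground truth.

# Coordinate and sequence conventions

All internal intervals are 0-based half-open; GFF3's 1-based inclusive
coordinates are converted exactly once at the I/O boundary
(`gff_to_internal()` / `internal_to_gff()`), which keeps off-by-one
errors out of the analysis code. Transcript-level analyses work in
transcription orientation; genomic intervals keep scaffold orientation
plus a strand flag. DNA is restricted to the A/C/G/T/N alphabet — other
IUPAC ambiguity codes are mapped to N with a warning, because the
exact-match read search in the gap filler needs a small alphabet.

# Alignment engines and scoring

Pairwise alignment is delegated to `Biostrings::pairwiseAlignment` with
two scoring regimes:

* **Local mapping** (contig-to-reference, genomic search): match +2,
  mismatch −3, gap open 5, gap extend 2 — the familiar BLAST-like
  defaults, appropriate for finding diverged homologous segments.
* **Global event calling** (`global_align()`, `finalize()`): same
  substitution scores but gap open 20. The reason is representational,
  not statistical: with open 5 the optimal global alignment interrupts a
  long gap (a several-hundred-bp retained intron) wherever the intron
  interior happens to match four or more consecutive exon bases, turning
  one biological event into a dozen small gap runs. With open 20 a split
  must be "paid for" by roughly ten consecutive matches, which is rare
  enough that in simulations at 15% divergence a planted intron is
  represented as a single run in 20 of 20 genes. Event calling needs this
  parsimonious representation; homology detection does not, so the local
  regime is left alone.

Identity is always reported as matches divided by alignment columns
*including gap columns*. Published pairwise-identity figures rarely state
their convention; this one is declared so the package's numbers are
reproducible against themselves.

# Curation

An ORF is an ATG followed by an in-frame stop within the contig, over all
six frames; ORFs running off the contig end do not count (a conservative
choice — a probabilistic coding-region model would recover more truncated
ORFs but needs training data). The filter keeps ORFs strictly longer
than 200 bp. Representative selection keeps the longest contig per
(assembly component, orthogroup) group, ties broken by lexicographically
smallest id so the result is deterministic; contigs without an
orthogroup assignment survive grouped by component alone. `Nxx` follows
the cumulative-sum definition. The UCO capture rate is reported truncated
(not rounded) to one decimal as a percentage, matching the convention of
published capture-rate tables (354/357 → 99.1).

# Expression analyses

FPKM is `count · 10^9 / (length · library total)`; it is invariant to
scaling a library's counts and satisfies `Σ FPKM·length/10^9 = 1` per
library. The log transform is `log2(FPKM + 1)`; the pseudocount keeps
zeros finite. Gene selection uses the unscaled MAD (no 1.4826 constant)
because only the ranking matters; ties break by gene id.

**Clustering.** Gene-gene distance is `1 − Pearson r` ("correlation
distance"), which clusters by expression *pattern* regardless of level;
trees use complete linkage (`stats::hclust`) and are cut at a
user-chosen `k`. The package deliberately does not auto-select `k`: the
number of transcriptional clusters is a judgment about the biology, so it
is a required parameter (default 9 in the pipeline config).

**Replicate QC.** Replicates of one sample should cluster together. For
each bootstrap resample of genes, libraries are clustered by correlation
distance with complete linkage; a library succeeds when the smallest
cluster containing it and at least one same-group replicate is no larger
than its replicate group. Support is the success fraction over
bootstraps; libraries under 0.5 are flagged. This plain bootstrap
co-clustering replaces multiscale-bootstrap AU p-values: the decision
being made — discard incoherent replicate libraries — only needs a
support fraction, and a label-permuted library (the canonical failure
mode, which preserves a library's count distribution while destroying
its correlations) receives support ≈ 0.

**Differential expression.** The DE component is a lightweight two-group
NB test, not a reimplementation of a full DE framework: median-of-ratios
size factors; per-gene method-of-moments dispersion pooled across the two
groups; moderation of that dispersion toward the median dispersion of
expressed genes (mean ≥ 5) with prior weight 12 — with 3v3 designs the
raw 2+2-df dispersion estimates are far too noisy to calibrate any Wald
test (a normal reference gives ~6% type-I error at nominal 1%; a t with
4 df collapses power); and a Wald statistic on the log2 fold change of
normalized means referred to a t distribution with residual + prior = 16
degrees of freedom. Under a matched NB null this yields a fraction of
p < 0.01 between roughly 0.006 and 0.012, and essentially complete
recovery of 4-fold changes at mean ≥ 100 under the standard
p < 0.01 / fold-change ≥ 2 thresholds. Genes with zero counts in both
groups report `log2fc = 0, p = 1`. Multiple testing uses
Benjamini–Hochberg throughout, as does the hypergeometric term
enrichment (upper-tail `phyper`).

**qPCR.** Technical replicates are averaged per sample and gene first;
ΔCT is the target CT minus the mean of the reference genes' CTs, and
relative expression is 2^−ΔCT.

# Reconstruction

`map_contigs()` aligns each contig on both strands as a *colinear chain*
of local alignments (best local hit, then recursion on the flanks). The
chain matters: a contig that spans a retained intron cannot be covered by
one affine local alignment — the gap would cost more than the second
flank earns — so it maps as two blocks and would otherwise lose half its
sequence. `stitch()` places contig bases at their reference-projected
positions, keeping contig-side insertions attached to the preceding
reference base (so planted events survive stitching), re-attaches the
contig bases between two same-contig blocks as an insertion at the
junction, and resolves disagreeing overlaps by alignment identity (ties
become N); overlaps disagreeing over more than 20% of their span raise a
conflict error rather than guessing. Uncovered reference spans become N
runs with provenance `gap`.

Two details concern the local aligner's habit of trimming diverged contig
ends (soft clipping): interior micro-gaps created this way are simply
left to the read filler, which operates at full coverage there; at the
transcript *termini*, where read coverage necessarily thins, clipped
bases are rescued by a one-to-one projection onto the flanking reference
positions — but only up to 40 bp, only into positions no aligned block
covers, and only when at least 40% of the projected bases match the
reference (so foreign sequence, e.g. a clipped-through intron, is never
projected).

`grep_extend()` is the read-based gap filler. Per gap and iteration, the
terminal `seed_len` (default 25) bases of the left then right flank are
used as exact-match seeds into the read pool (both strands by default);
matching reads are extended inward column by column where at least
`min_read_support` (default 2) reads agree and the majority is strict — a
support tie halts the gap, reporting ambiguity instead of guessing. A gap
closes when the converging extensions overlap exactly over at least
`seed_len` bases (preventing chimeric fills); terminal gaps close when
the single flank has recovered the full gap length. Non-gap bases are
never modified, and per-base provenance records the iteration that added
each base. With read length 100 and seed 25 each iteration advances up to
75 bp per side, which is why a gap of ~2.5 × (read_len − seed_len) with
one-sided extension closes in exactly three iterations.

`genome_recover()` chains local alignments of a query CDS against genomic
scaffolds on both strands, splits candidate exons at genome-side gap runs
≥ 20 bp, and snaps interior boundaries to GT..AG dinucleotides within
±10 bp. The donor and acceptor of one intron are snapped *jointly* under
a query-contiguity constraint (shifting one end shifts the other by the
same amount minus any query overlap), which returns exon bases the
aligner parked at the wrong end of an intron. The coding frame is chosen
as the six-frame translation of the spliced exons maximizing the BLOSUM62
alignment score against the query peptide. A locus scoring below
threshold is reported as an explicit not-found result — absence of
evidence is distinguished from a poor hit.

`finalize()` trims the reconstructed sequence to the span matching the
reference start codon through terminal stop using the high-open global
alignment (internal insertions are kept), emits the translation, and
flags — rather than silently trims — a missing ATG, remaining N runs, or
a premature stop.

# Pseudogene scan

`detect_indels()` turns each maximal gap run of the global alignment into
one event: gaps in the reference row are insertions, gaps in the query
row deletions; the reference position is the 0-based coordinate of the
base preceding the run, and `frame_offset = length mod 3`.
`detect_premature_stop()` anchors the query frame at the base aligned to
the reference ATG and scans codons; a stop is premature only if its
alignment column lies strictly before the reference's terminal stop
column, and the truncated fraction of the reference protein is reported
(positions are given both as 0-based CDS coordinates and 1-based
alignment columns, since published "position" figures rarely state their
convention). `detect_retained_intron()` reclassifies insertions sitting
at annotated exon junctions whose length matches the annotated intron
within ±5%; nearby insertion runs (≤ 15 aligned columns apart) are first
clustered and tested as one event, because even the high-open aligner
occasionally splits a very long insertion once. The junction window is
±12 bp: at 15% flank divergence the optimal alignment can slide a long
gap by around ten bases from the true junction, so a ±2 window rejects
genuine retained introns while the ±5% length match remains the decisive
signature. GT..AG termini of the inserted sequence are recorded as
corroborating evidence but not required (the gap slide usually shifts
them). When reads are supplied, an event is marked read-supported if at
least `min_read_support` reads contain the variant with 15 bp of context;
events longer than a read length legitimately report no support.

`classify()` is a pure function of the event set: a frameshift indel with
a downstream premature stop truncating at least 5% of the reference
protein is a `frameshift_pseudogene`; otherwise a retained intron gives
`retained_intron` (splicing defects outrank the stops they often
introduce); otherwise a premature stop gives `truncated`; in-frame indels
give `in_frame_variant`; nothing gives `conserved`. The 5% truncation
threshold keeps near-terminal polymorphic stops from becoming pseudogene
calls.

# The synthetic-data module

The generators are pure functions of their seed (the caller's RNG state
is saved and restored), so every artifact is byte-reproducible.

* `simulate_gene_models()` builds one gene per scaffold: 7–12 exons of
  90–300 bp by default (matching the exon counts of the reference genes
  the workflow targets), GT..AG introns of 80–800 bp, a CDS that starts
  ATG, ends in a single stop and has length divisible by 3, and a random
  strand.
* `simulate_ortholog()` applies i.i.d. substitutions at the configured
  rate — only outside planted-event footprints, never in the first or
  last codon, and never turning a sense codon of the reference frame into
  a stop, so premature stops in the mutant are attributable to planted
  events alone. Divergence 0.15 mimics a well-conserved ortholog pair
  (~85% CDS identity), 0.27 a more distant one (~73%). Planted events are
  insertions/deletions inside exons and retained introns (the annotated
  intron sequence inserted at its junction). Fragmentation produces
  contigs of at least 200 bp (assemblers do not report shorter ones) with
  breakpoints at least 25 bp from planted events, so event detection is
  attributable to the scanner rather than the stitcher, and one internal
  gap interval whose coordinates are recorded in both mutant and
  reference frames.
* `simulate_reads()` produces fixed-length paired fragments at uniform
  positions; with error rate 0 every read is an exact substring of the
  transcript or its reverse complement.
* `simulate_counts()` draws gene baselines log-normally (median ~300) and
  assigns each gene to one of `k` archetypes — ±amplitude (default 2.5
  log2 units) tissue patterns drawn from the even-parity code over
  tissues, so any two archetypes differ in at least two tissues and
  pattern correlations stay ≤ 1 − 4/n_tissues. Counts are NB with
  dispersion 0.05 by default (0 gives Poisson). Outlier libraries are
  within-library permutations of gene labels.

What the generator does *not* emulate: positional and GC coverage bias,
base-quality error profiles, isoform structure, paired-end insert-size
variation, non-canonical splice sites, and genuinely overlapping gene
models. Passing tests therefore demonstrate the correctness of the
algorithms under clean, well-separated conditions, not performance on
real libraries — e.g. real replicate outliers are rarely as extreme as a
label permutation, and real assemblies contain chimeric contigs the
conflict check can only flag, not repair.

# Problem sizes and determinism

The test suite runs the full reconstruction-plus-scan path on 20
simulated genes (CDS ~1.5–3.5 kb, 3 contigs, 120-bp gap, 20× reads),
clustering on 6000 genes × 18 libraries with the top 4000 by MAD, QC
with up to 1000 bootstraps, and DE calibration on 3000-gene 3v3 designs —
sizes chosen so the whole suite completes in a couple of minutes while
keeping the binomial noise on measured fractions well inside the asserted
bands. The pipeline derives per-stage seeds from one global seed by
stable hashing of stage names, so toggling one stage never changes
another stage's randomness.

# Known limitations

* The ORF scanner requires a complete ATG..stop span; genes truncated by
  the contig boundary are not counted as coding.
* Gap filling is greedy single-path consensus; a true repeat longer than
  the seed can halt a gap (reported as unfilled) but will not be
  mis-assembled.
* Retained-intron calls need an annotated reference gene model; without
  one, insertions stay insertions.
* The DE component is a calibrated stand-in for two-group comparisons,
  not a general linear-model framework; users with complex designs should
  export counts to a dedicated package.
* `genome_recover()` assumes colinearity between query and locus; it will
  not recover rearranged or trans-spliced genes.
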