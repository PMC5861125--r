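---
title: "Methods: quantitative multiplexed CLIP analysis with uvclap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative multiplexed CLIP analysis with uvclap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvclap)
library(dplyr)
```

# The problem

CLIP-style experiments map where an RNA-binding protein (RBP) touches the
transcriptome: cells are UV-irradiated so that protein–RNA contacts become
covalent, the protein is purified, and the attached RNA fragments are
sequenced. Two chronic difficulties are (i) PCR amplification, which
multiplies some cDNAs far more than others and destroys quantitative
information, and (ii) the nonspecific background, which can only be
interpreted quantitatively when signal and mock-control libraries are
amplified and sequenced *together*. uvCLAP addresses both by multiplexing
all libraries of an experiment with a three-level barcode before
amplification:

* a **condition tag**: a fixed 5-nt DNA tag from an error-correcting
  codebook with minimum pairwise Levenshtein distance 3, identifying the
  pulldown condition;
* a **replicate tag**: a *semi-random* 5-mer drawn from one of the IUPAC
  patterns `DRYYR` or `DYRRY` (D = not C, R = purine, Y = pyrimidine);
  its class identifies the biological replicate while its realization adds
  UMI capacity;
* a **size-fraction index**: a commercial PCR index, handled as ordinary
  Illumina index demultiplexing via the sample sheet.

The condition tag is interleaved with five random bases on the 5' end of
mate 1 as `NNNTTTTTNN`. The five random bases (1024 combinations) together
with the realized replicate 5-mer (48 combinations) form the unique
molecular identifier (UMI), giving 49,152 distinguishable molecules per
genomic position; using both mate start coordinates extends this further.

This package implements the complete computational side of that design on
plain tabular data: barcode design and validation, error-correcting
demultiplexing, UMI-based crosslinking-event calling, quantitative
signal-versus-control analysis, genomic target-class annotation,
exon-junction metaprofiling, and a fully seeded synthetic-data generator
that provides ground truth for every stage.

# Barcode design

`generate_edit_distance_tags()` performs a greedy construction over a
seeded shuffle of all 4^5 candidates, accepting a candidate when its
Levenshtein distance to every accepted tag is at least `min_dist`
(default 3). Distance 3 guarantees unique nearest-neighbour correction of
one substitution *or* one indel (spheres of radius 1 around codewords are
disjoint). Two filters reflect sequencing chemistry:

* candidates containing a homopolymer run of three or more identical
  bases are excluded up front ("polybases" — homopolymers are both
  error-prone on the sequencer and ambiguous under indels);
* `filter_tags()` removes tags whose first two or last two bases are
  identical, and tags whose reverse complement occurs inside the adapter.

Two interpretation points were genuinely open and are fixed as follows.
"Nucleotide repetitions at either end" is read as *the terminal two bases
being identical* (the minimal reading; any-terminal-run is a stricter
subset and can be obtained by pre-filtering). Adapter
reverse-complementarity is read as a full-tag substring match against the
adapter. "Self-complements" cannot mean literal reverse-complement
palindromes for odd-length tags; the optional
`forbid_self_complement = TRUE` instead rejects a candidate whose reverse
complement is already in the accepted set, which is the collision that
matters during ligation. Two-channel colour balance
(`check_color_balance()`) uses the convention red = {A, C},
green = {G, T}; the assignment is configurable because chemistries name
channels but not base sets.

The codebook produced for a given seed is deterministic but is *not* the
published tag list of any particular kit or paper — it is a set satisfying
the same constraints, which is what decoding correctness depends on.

# Demultiplexing

`demultiplex_reads()` slices the mate-1 prefix into random positions
(1–3, 9–10) and tag positions (4–8), decodes the condition tag by
nearest-neighbour Levenshtein decoding (`correct_tag()`), assigns the
mate-2 5-mer to its replicate pattern by counting per-position IUPAC class
violations (`assign_pattern()`, at most one violation tolerated: the two
default patterns disagree on four positions, so a single substitution can
never cross patterns), clips the fixed read-through lengths (5 nt from
mate-1 3' ends, 10 nt from mate-2 3' ends — the clipped bases always exist
on the other mate, so no insert information is lost), and assembles the
UMI as the five 5' random bases plus the realized 3' 5-mer.

Whether the realized 3' tag should contribute to the deduplication UMI or
only to capacity accounting is not decidable from the protocol
description; both contribute to the stated 49,152-event capacity, so the
default includes it (`umi_mode = "both"`), with `"five_prime"` available.

**Indels inside a read.** The single-error correction guarantee is a
property of the codebook and holds exhaustively when the corrupted tag is
decoded as a sequence (this is verified by exhaustive corruption in the
test suite). Inside a full read the tag/insert boundary is unknown: the
decoder therefore scores boundary hypotheses at shifts −1, 0, +1 and
ranks them by (edit distance, |shift|). Preferring the zero-shift
explanation matches the predominance of substitution errors on Illumina
sequencers; an indel hypothesis for tag *t* can tie, at distance 1, with a
substitution hypothesis for a different tag *t'* whenever the codebook
contains a pair at distance exactly 3, so in-read indel recovery is
best-effort (ties across different tags are routed to UNASSIGNED rather
than guessed). All in-read substitutions decode exactly.

# Event calling

After alignment (external, splice-aware or not — alignments enter as a
plain table with a `multimap` flag; for bowtie2 output the flag
corresponds to the `XS:i` auxiliary tag), `call_events()` applies:

1. `filter_unique()` — multi-mapping reads are dropped;
2. `collapse_to_events()` — alignments sharing UMI and the start
   coordinates of both mates are one molecule; `read_count` records the
   group size;
3. `filter_spurious()` — within each group of events at the same mapped
   position, events with fewer than 10% of the reads of the strongest
   event are removed. UMI sequencing/amplification errors create sibling
   events with *identical* mapping, which is exactly this group; the
   boundary is strict (`<`), so an event at exactly 10% is retained, and
   the strongest event of a group can never be removed;
4. `crosslink_position()` — reverse transcription predominantly stops at
   the crosslinked nucleotide, so the default `"upstream"` convention
   places the crosslink one nucleotide 5' of the cDNA in genome
   coordinates (`mate1_start − 1` on the plus strand, the position just
   past the fragment end on the minus strand). Because the underlying
   truncation-vs-readthrough chemistry is protocol-dependent, the
   `"start"` (read-start) convention is also provided.

All coordinates are 0-based half-open internally; BED is emitted natively
and GTF/GRanges conversion happens only at the I/O boundary.

# Quantification

Because all libraries of a run are amplified and sequenced together,
event totals are directly comparable:

* `total_enrichment()` — the signal/control ratio of total events
  (replicates combined). An empty control is reported as a flagged
  infinity rather than hidden behind a pseudocount, because the raw ratio
  is the quantity of interest; a pseudocount mode would bias exactly the
  low-background libraries it is meant to rescue.
* `bin_counts()` — 100-nt bins anchored at coordinate 0,
  strand-collapsed by default (stranded mode available); each event falls
  in exactly one bin, so totals are conserved.
* `ma_table()` — per-bin mean log2 count and log2 fold change for bins
  with at least 2 events in both replicates, with the median log2 fold
  change as the summary. Raw counts are the default since the comparison
  is between jointly amplified replicates.
* `median_ratio_factors()` — the standard median-of-ratios size-factor
  estimator (per-bin counts over the bin's cross-library geometric mean,
  median per library, over bins with nonzero counts everywhere). It is
  cross-checked against DESeq2's implementation in the test suite. Note
  that scaling one of *k* libraries by *c* scales its factor by
  c^(1−1/k) — the geometric-mean reference rescales too — so factor
  *ratios* are exactly scale-equivariant, and planted factors with
  geometric mean 1 are recovered exactly.
* `call_enriched_bins()` — a deliberately simple enriched-bin caller
  (normalized fold-change threshold, minimum events, binomial test
  against the library-size expectation, Benjamini–Hochberg, adjacent
  qualifying bins merged). It is pipeline plumbing standing in for
  dedicated peak callers, which are out of scope; BH was chosen because
  it is the standard for this kind of screening.

# Annotation

`assign_target_class()` gives every peak exactly one label, the
highest-priority class it overlaps by at least one nucleotide on the same
strand, in the fixed order rRNA > ncRNA > pseudogene > 3'-UTR > 5'-UTR >
exon > intron > antisense > intergenic. No fractional-overlap threshold
is applied because none is part of the scheme. A peak overlapping a
3'-UTR of one gene and a coding exon of another takes the 3'-UTR label —
pure priority. ncRNA means any gene biotype that is not protein-coding,
not rRNA, and not pseudogene-like.

`standardize_and_merge()` extends peaks shorter than 41 nt symmetrically
about their midpoint, then merges overlapping or abutting intervals. The
extension-first order follows the stated procedure; for an odd extension
the extra base goes 3' (a deterministic rule is needed and the choice is
otherwise inconsequential). `overlap_sets()` counts merged-universe
regions per membership combination (the numbers behind a Venn diagram),
`peak_control_proximity()` classifies peaks by a strict > 50 nt
edge-to-edge gap to the nearest control read, and `motif_occurrence()`
scans strand-oriented peak sequences for degenerate IUPAC motifs such as
the QKI consensus `AYUAAY`.

# Junction metaprofiles

`extract_junctions()` emits one deduplicated junction per adjacent exon
pair; `junction_histogram()` accumulates signed transcript-direction
distances of crosslinks to junctions, with position −1 defined as the
last exonic nucleotide 5' of the junction. Counting is restricted to the
exonic flanks, and a crosslink near several junctions counts once per
junction by default (`"nearest"` mode available) — with per-junction
counting, a binding site 20–30 nt upstream of one junction also appears
~120–130 nt downstream of the preceding junction when the same exon is
both flanks, which is visible as a small secondary band in dense
annotations. `uniformity_statistic()` quantifies the flat-versus-peaked
contrast with a chi-square goodness-of-fit against uniformity over the
window; exon-junction-complex-type binding concentrates mass at −30…−20
and rejects decisively, while stochastic background rejects at the
nominal rate.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all randomness derives from
one master seed with documented per-stage offsets, so every stage is
individually reproducible. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 100 kb, GC 0.5 | smallest size that holds a full gene complement with realistic spacing |
| genes | 20 coding (4 exons of 150 nt, 300-nt introns, 60/80-nt UTRs), 2 rRNA, 4 ncRNA, 3 pseudogene | exercises every annotation class and yields 60 junctions |
| binding modes | `motif` (AYUAAY), `junction_upstream` (centres uniform 20–30 nt upstream), `utr5`, `none` | mirror sequence-specific KH-domain binding, EJC deposition, and cap-complex 5'-UTR binding |
| libraries | 2 conditions × 2 replicates, 4000 signal molecules, signal:control 10 | a typical well-enriched RBP; the ratio is the planted truth that `total_enrichment()` must recover |
| fragment length | round(N(50, 12)) clamped to 24–80 nt | mid-size-fraction cDNA length scale |
| duplication | geometric extra copies, mean 0.6, ×4 inside 40–60 nt | the simplest mechanism that reproduces the observed excess of duplicates for mid-length cDNAs |
| error rate | 0.001/base | Illumina-scale substitution errors; indels are not simulated |
| control background | uniform over gene bodies with 20% of mass on rRNA genes | stochastic background with the rRNA prominence seen in real controls |

Reads carry full read-through into the opposite barcode (mate 2 is the
exact reverse complement of mate 1), which is the worst case for the
fixed clipping step and makes the demultiplexer's output exactly
comparable to truth. Quality strings are constant; quality modelling is
out of scope. What the generator does **not** emulate: indel sequencing
errors, splice-junction-spanning reads (alignments are derived from truth
coordinates), non-uniform genome composition, and transcript-abundance
heterogeneity. Tests passing on this generator therefore validate the
*logic* of the pipeline (grouping rules, boundary conditions, coordinate
conventions, estimator algebra), not its robustness to every artefact of
real libraries.

# Numerical and boundary choices

* Strict inequalities where the procedure states them: the spurious
  filter removes `< 10%`, proximity requires `> 50 nt`.
* `filter_spurious(threshold = 0)` is the identity; `collapse_to_events()`
  is idempotent and order-invariant (output is coordinate-sorted).
* Crosslink positions that would fall below coordinate 0 are clamped and
  flagged rather than dropped.
* Correlations with fewer than 3 included regions are refused (`NA` with
  a warning); the relative standard deviation of a single value is 0 with
  a warning; a zero mean makes it `NA`.
* `median_ratio_factors()` errors with advice when no bin has nonzero
  counts in every library.
* Ties in nearest-neighbour tag decoding (possible only when the
  codebook violates the distance precondition) give UNASSIGNED, never an
  arbitrary winner.

# Problem sizes

The test suite runs the grouping-oracle comparison at 10^5 random
alignment records, the demux round-trip exhaustively over every single
edit of every codebook tag, junction profiling at ≥10^4 events, and the
uniformity calibration over 200 seeds at 1500 events each; these sizes
give stable statistics while keeping the whole suite fast on one CPU.

# Known limitations

* In-read indel correction is best-effort (see the demultiplexing
  section); the exhaustive guarantee applies to tag-sequence decoding.
* The enriched-bin caller is plumbing, not a replacement for a dedicated
  peak caller with a proper count model.
* Annotation is not transcript-isoform-aware: UTR and exon intervals are
  taken as annotated, and introns are gene body minus exons.
* Alignments are consumed, never produced; SAM-dialect specifics beyond
  the `multimap` flag are the upstream aligner's concern.
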