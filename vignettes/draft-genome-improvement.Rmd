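---
title: "Reference-assisted improvement of draft bacterial genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-assisted improvement of draft bacterial genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftweaver)
```

## The problem

Short-read de novo assemblies of bacterial genomes arrive as dozens to
hundreds of contigs separated by two kinds of gaps: *physical* gaps, where no
read spans the junction and even the adjacency of the flanking contigs is
unknown, and *sequence* gaps, stretches represented as runs of N whose length
the assembler guessed — often wildly, since paired-end insert sizes bound the
real distance. When one or more genomes of closely related strains are
available, most of this uncertainty can be resolved in silico: contig ends
that land close together on a relative's genome were probably adjacent; an
N-run whose flanks map a known distance apart on the relative can be resized
to that distance; and contigs can be ordered and oriented along the relative
for comparative work. draftweaver implements that workflow as composable R
functions, together with the diagnostics that usually accompany it (assembly
congruency checks, unique k-mer synteny plots, GC/GC-skew tracks, and
promoter-box profile scanning) and a simulator that manufactures truth-known
test fixtures.

The package deliberately separates *evidence gathering* (gap candidates, join
proposals, with full provenance) from *evidence application* (`apply_joins`,
`resize_nruns`), so every automated decision is inspectable and reversible —
in real projects the candidate table is what goes to PCR validation, not
straight into the final sequence.

## The gap-closure model

All numeric rules live in one `thresholds()` object:

* 300 bp of sequence is extracted from each end of every contig strictly
  longer than 1 kb (`end_len`, `min_contig_for_ends`). Shorter contigs are
  too likely to be repeat debris to seed joins.
* An alignment qualifies as evidence when its E-value is at most 0.02
  (`max_evalue`). E-values use the Karlin–Altschul form
  $E = K m n e^{-\lambda S}$ with ungapped parameters
  ($\lambda = 1.28$ per score unit, $K = 0.46$ for +1/−2 scoring) applied to
  gapped scores — a standard approximation; only the 0.02 cutoff matters
  downstream, and all parameters are settable in `scoring_scheme()`.
* Two ends become a gap candidate when their best non-ambiguous hits land on
  the same reference sequence, facing each other, with inner alignment
  boundaries at most 1 kb apart (`max_ref_separation`). "Inner boundaries"
  is our reading of "regions no more than 1 kb apart": the distance between
  the facing edges of the two alignments, which is what the physical gap
  physically is. The implied gap subtracts each end's unaligned gap-side
  overhang, since those bases are real sequence.
* Contig merges require 15 bp or more of perfect suffix–prefix identity
  (`min_overlap`) *and* prior reference adjacency — exact short overlaps
  arise by chance, so the co-condition is not optional.
* N-runs strictly longer than 300 (`nrun_min_to_touch`) are resized: to the
  reference-implied distance when both 300 bp flanks map consistently to one
  reference sequence within 50 kb of each other, otherwise to exactly 300 N
  (`nrun_cap`), the upper bound a 300 bp paired-end library can support. The
  50 kb flank-separation ceiling guards against flanks straddling a
  rearrangement; it is our own bound, set comfortably above the largest gap
  artifacts we emulate (>10,000 N), and configurable.
* Both 1 kb and 300 N rules are strict inequalities; boundary behaviour is
  pinned by tests (a 1,000 bp contig yields no ends, a 300 N run is
  untouched, a separation of exactly 1,000 qualifies and 1,001 does not).

`apply_joins` consumes each contig end at most once. Conflicts resolve by
evidence class — exact overlap > shared reference gene > plain reference
adjacency — then score, then lexicographic contig id so reruns are
deterministic; an edge that would close a ring is rejected (reported as a
broken cycle), since bacterial chromosome circularity should be asserted by
the analyst, not inferred from one weak join.

## The seeded aligner

The local aligner is self-contained so the pipeline has no external binary
dependency: exact 11-mer seeding on both strands, X-drop ungapped extension,
then a full affine-gap Smith–Waterman (match +1, mismatch −2, gap open 5,
extend 2) over a subject window spanning each seed cluster's diagonals. The
window always covers the cluster by a full query length on each side, so
whenever query and subject share an exact seed word the windowed score
equals the exhaustive quadratic-time score — a property the test suite
verifies against `smith_waterman()` on hundreds of random pairs at 0–20%
divergence, and `smith_waterman()` itself is cross-checked against the
independent implementation in `Biostrings::pairwiseAlignment`. Queries whose
qualifying hits scatter over more than five distinct subject regions are
flagged ambiguous and excluded from join evidence: near-unique placement is
the silent assumption of the whole procedure, and repeats must not seed
false joins.

## Reordering, synteny and congruency

Ordering and orienting scaffolds does not need full whole-genome alignment:
a 25-mer that occurs exactly once in the scaffold set and exactly once in
the reference (counting both strands as one entity — a k-mer and its reverse
complement are the same object, and palindromes are excluded) is an
unambiguous coordinate anchor. A scaffold longer than 1 kb with at least 3
anchors is placed at the median anchor coordinate with the majority anchor
strand; an exact 50/50 strand split leaves it unplaced rather than guessed.
`min_anchors = 3` and the majority rule are our choices where the procedure
is otherwise unspecified; the median makes placement robust to a minority of
anchors displaced by local rearrangement. The same unique-k-mer machinery
drives the synteny dot plots (one point per shared unique 25-mer, perfect
matches only) and windowed GC%/GC-skew tracks use 10 kb windows at 5 kb
steps by default — a resolution that shows the replication origin/terminus
skew flip in a ~6 Mb chromosome without drowning it in noise.

Congruency checking compares independent assemblies of the same reads: a
contig is supported when ≥95% of its length is covered at ≥99% identity by
alignments to a *single* contig of another assembly. Stitching coverage
from different contigs would let a chimera vouch for itself, which is
exactly the misassembly class the check exists to catch; an assembly with an
unsupported contig ≥10 kb is marked for culling. All three numbers are
configurable; they are our operating points, since the procedure they
implement was published without numbers.

## Promoter-box scanning

The motif module is an ungapped position log-odds profile, not a full
profile HMM: the boxes it models are essentially fixed-length (27 bp with
rare one-base variants), so match/insert/delete states would add parameters
without adding discrimination; a full HMM is a documented extension point.
Column probabilities use pseudocount 0.5 against a background of the target
genome's mononucleotide frequencies; scores are summed log2 odds (bits), and
windows on both strands at or above the 3.0-bit floor are reported, with
overlapping same-strand windows collapsed to the best. Because the null
model is explicit and ours, absolute bit values are not comparable to
scores from other tools' null models — the floor and the downstream filter
are what carry over. That filter keeps a hit only when a CDS start lies
0–500 bp downstream of the box end on the same strand (inclusive at 500),
the conventional semantics of promoter-distance tables.

## What the simulator emulates — and what it does not

`simulate_fixture()` manufactures: an i.i.d. genome at a target GC (default
60.6%, a typical pseudomonad value); a diverged relative (substitutions,
1–5 bp indels, optional inversions); a fragmentation into contigs with known
adjacencies and true gap sizes 0–2,000 bp (drawn uniformly — gaps beyond the
default 1 kb pairing ceiling are deliberately present, so pipeline runs on
this fixture raise `max_ref_separation` to cover them while separate
boundary tests pin the default); corrupted scaffolds in which every true
gap is replaced by 10,000 N (the observed artifact shape); a scrambled
assembly with 40% of contigs reverse-complemented; and planted genes with
promoter boxes sampled from a trained profile 0–500 bp upstream. Training
sets for the profile come from `sim_motif_training()` at 8% per-position
divergence from a consensus — calibrated so the resulting profile has the
sharpness of real sigma-factor boxes, whose genome-wide chance-hit density
at a 3-bit floor is on the order of one per hundred kb of scanned windows.

The i.i.d. background is the important idealisation: real genomes contain
rRNA operons, IS elements and NRPS-like repeats that produce exactly the
ambiguous placements the repeat guard exists for. Passing fixtures therefore
demonstrates correctness of the *rules*, not robustness to repeat-rich real
data; the ambiguity guard is tested directly with tandem-duplicated
sequence instead. Read-level error simulation is out of scope — assembly
itself is upstream of this toolkit.

Every random step takes a mandatory seed and derives fixed small offsets for
sub-steps, so one seed reproduces the entire bundle bit-exactly;
`write_fixture()` stores the configuration beside the data.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; FASTA/GFF3/AGP I/O is 1-based
  inclusive per those standards. The conversion happens only at I/O.
* Non-ACGTN IUPAC codes become N on ingest (counted and logged); ambiguous
  bases never reach alignment code and always score as mismatches.
* N50 ties: the contig at which the descending cumulative sum first reaches
  half the total defines both size and number.
* Coverage folds round to the nearest integer, as coverage tables print.
* A gap of length L costs gap_open + L·gap_extend, matching the
  `Biostrings` convention so the oracle cross-check is exact.
* Resize projections that imply overlap floor at 1 N with an overlap flag;
  runs flush against a scaffold boundary are warned about and left alone.
* GC-skew is defined 0 (and flagged) in windows with no G or C.

## Problem sizes

The shipped tests run the full round trip on a 500 kb genome in 20 contigs
(the scale at which every rule, including the 50 kb resize ceiling and
multi-kb gaps, is exercised while a laptop run stays in minutes), the
aligner oracle on 200+ random pairs of 50–200 bp, synteny on 100–120 kb
sequences, and motif recall on a 100 kb background with 20 planted
instances. Larger inputs change nothing structurally: index construction and
scanning are linear in sequence length, and the quadratic Smith–Waterman
only ever sees 300 bp ends against few-kb windows.

## Known limitations

* Gap pairing is nucleotide-level; the shared-gene rule does not use
  translated homology, so it can miss anciently diverged gene links.
* The reorderer assumes overall collinearity with the reference; it orders
  and orients but does not detect rearrangement breakpoints, and a scaffold
  spanning an inversion boundary is placed at its median anchor, which may
  sit on either side.
* Karlin–Altschul parameters are ungapped approximations; E-values are
  honest rankings but not calibrated p-values for gapped alignments.
* The congruency check is pairwise coverage, not a full multi-alignment; a
  misassembly shared by all assemblies is invisible to it by construction.
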