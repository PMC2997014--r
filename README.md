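# draftweaver

Reference-assisted improvement of draft bacterial genome assemblies, in R.

Short-read de novo assemblies arrive as a pile of contigs separated by
*physical* gaps (no read spans the junction; even adjacency is unknown) and
*sequence* gaps (N-runs whose length the assembler guessed, often by orders
of magnitude). When genomes of related strains exist, most of that
uncertainty is resolvable in silico. draftweaver packages that workflow for
people finishing bacterial genomes:

* **Gap candidate discovery** — 300 bp of sequence from each end of every
  contig > 1 kb is aligned to the reference genomes with a self-contained
  seeded local aligner (exact 11-mer seeds, X-drop extension, affine-gap
  Smith–Waterman; Karlin–Altschul E-values `E = K·m·n·e^(−λS)`). Two ends
  whose best hits (E ≤ 0.02) land on the same reference sequence, facing
  each other, ≤ 1 kb apart, become a gap candidate with an implied gap size.
* **Contig joining** — exact suffix–prefix overlaps (≥ 15 bp, 100% identity,
  reference-adjacent pairs only), shared-reference-gene end pairing, and
  plain reference adjacency, applied by rank with per-end exclusivity and
  cycle breaking.
* **N-run resizing** — runs > 300 N are set to the distance their flanks
  imply on the reference, or capped at 300 N (the paired-end insert bound)
  when the flanks don't map.
* **Reference-guided reordering** — scaffolds are ordered/oriented by unique
  25-mer anchors (double-stranded uniqueness, perfect matches only, median
  position, majority strand).
* **Diagnostics** — cross-assembly congruency checking (chimera detection),
  unique 25-mer synteny dot plots, windowed GC% and GC-skew tracks, and
  promoter-box profile training/scanning (bit-score floor, upstream-of-CDS
  distance filter).
* **A truth-known simulator** — genome, diverged reference, fragmented
  assembly, corrupted N-runs, planted genes/motifs, with full truth tables,
  so the whole pipeline is testable offline.

## Worked example

Simulate a 60 kb genome cut into 6 contigs (gaps 0–1000 bp, 40% of contigs
reverse-complemented, every gap corrupted to 10,000 N), then run the
pipeline against the reference:

```r
library(draftweaver)

cfg <- sim_config(genome_len = 60000, n_contigs = 6, gap_len = c(0, 1000),
                  seed = 42)
fix <- simulate_fixture(cfg)
idx <- build_seed_index(c(reference = fix$reference))
th  <- thresholds()

cand <- find_gap_candidates(extract_ends(fix$assembly, th), idx, th)
cand[, c("contig_a","side_a","contig_b","side_b","separation","implied_gap")]
#>   contig_a side_a contig_b side_b separation implied_gap
#> 1    c0004  right    c0005   left        928         928
#> 2    c0005  right    c0006  right         61          61
#> 3    c0003   left    c0004   left        498         498
#> 4    c0002  right    c0003  right        106         106
#> 5    c0001  right    c0002   left        592         592
```

All five true adjacencies are recovered with their exact gap sizes (the
sides reflect each contig's stored orientation after scrambling). Applying
the joins chains everything into one scaffold:

```r
joined <- apply_joins(fix$assembly, candidates_to_proposals(cand))
joined$scaffolds[[1]]
#> scaffold scaffold_0001: c0006(+) - gap:61N - c0005(-) - gap:928N - c0004(-)
#>   - gap:498N - c0003(+) - gap:106N - c0002(-) - gap:592N - c0001(-)
```

Resizing the corrupted scaffold restores every 10,000-N artifact to its true
size, and reordering recovers the genome order and orientation:

```r
resize_nruns(fix$scaffolds, idx, th)$report
#>   scaffold_id start old_n new_n           rule
#> 1  scaffold_1  9352 10000   592 reference_span
#> 2  scaffold_1 29874 10000   106 reference_span
#> 3  scaffold_1 48892 10000   498 reference_span
#> 4  scaffold_1 68135 10000   928 reference_span
#> 5  scaffold_1 88665 10000    61 reference_span

ro <- reorder_scaffolds(anchor_scaffolds(fix$assembly,
                                         c(reference = fix$reference)),
                        nchar(fix$assembly$seqs), th)
ro$placements
#>   scaffold_id reference_id position orientation n_anchors
#> 1       c0001    reference   4663.5           +      9328
#> 2       c0002    reference  15192.5           +     10498
#> 3       c0003    reference  25068.5           -      8994
#> 4       c0004    reference  34697.0           +      9219
#> 5       c0005    reference  45511.5           +     10506
#> 6       c0006    reference  55412.5           -      9126
```

`old_n` of 10,000 versus `new_n` of 61–928 is the whole point: the N-runs
now reflect reference-implied distances instead of assembler artifacts.
Assembly summary statistics (N50 size/number, contigs over a cutoff) come
from `length_stats()`.

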