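---
title: "CRISPR spacer-based phage-host linkage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR spacer-based phage-host linkage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrylink)
```

## The scientific problem

Bacterial CRISPR arrays store short sequences ("spacers") copied from the
genomes of past invaders between near-identical direct repeats. Because
repeat sequences are conserved within a bacterial species while spacers
record that species' individual infection history, spacers mined from a
metagenome can be assigned to a host taxon by the repeat they sit next to,
and then matched against assembled phage genomes to infer who infects
whom. Around that core inference, the same data support several companion
analyses: per-genome abundance profiles, the localized diversification of
phage genome regions under CRISPR targeting, and the detection of
phage-to-host horizontal gene transfer (HGT) from coverage anomalies and
repeat footprints.

`berrylink` implements this chain for low-diversity communities — systems
with a handful of dominant bacteria and a tractable set of phages, of
which macroscopic sulfur-cycling aggregates from salt marshes are a
natural example. Every stage is exercised end to end on a synthetic
community with a machine-readable truth table, so the pipeline's claims
are tested against known ground truth rather than against a fixed corpus
of downloads.

## Pipeline model, stage by stage

### Quality trimming

`quality_trim()` applies the conventional staged rule: adapter clip
(exact match, cut from the leftmost adapter start), removal of
leading/trailing bases below quality `end_q = 2`, then a 5'→3' sliding
window of `window = 4` bases; at the first window whose mean quality
falls below `min_avg_q = 15` the read is cut at the first *individual*
base below that threshold inside the window (a failing window always
contains one — if every base were at or above the threshold, so would be
the mean). Reads shorter than `min_len = 100` after trimming are
discarded. Cutting at the first low base rather than at the window start
retains high-quality bases at the boundary and makes the operation
idempotent. The Phred encoding is Sanger +33; the adapter list is empty
by default because the simulator does not add adapters.

### CRISPR array detection

`detect_arrays()` is a CRT-style detector. An exact `seed_k = 8`-mer
recurring at a spacing compatible with one repeat plus one spacer
(defaults: repeat 19–48 nt, spacer 18–60 nt, so spacing 37–108 nt) seeds
a chain of array units, greedily extended across the genome. The seed is
then widened into the full repeat, column by column on each side. A
column is accepted when at most `min(max_repeat_mismatch, floor(0.1 n))`
of the `n` copies disagree with the column majority *and* no copy
accumulates more than `max_repeat_mismatch = 2` total mismatches against
the consensus. The fraction-based cap needs a comment: a rule of the form
"extend while `(n - max_mm)/n` of copies agree" degenerates for small
arrays (with `n = 3` and `max_mm = 2` it accepts every column, because
the majority base always reaches 1/3), so the per-column cap is tied to
10% of the copy number, which reduces to near-unanimity for small arrays
and still tolerates single degenerate copies in long ones. On error-free
genomes this recovers planted repeat boundaries exactly, which the
read-level spacer miner depends on; on real genomes with mutated repeat
ends it will report the conserved core, which is the part a read-anchored
miner can use anyway.

Two guards matter in practice. Overlapping calls seeded from different
k-mers of the same repeat are merged (the call with more units wins). And
pure tandem repeats are rejected: a tandem repeat of period *p* chains
every other unit into a legal-looking "array" of period 2*p* whose
spacers are all copies of one another, so arrays in which at most half
the spacers are unique are discarded — genuine spacers are unique by
construction of the immune mechanism.

Consensus columns take the majority base with alphabetical tie-breaking;
detection is single-strand because a repeat array is its own footprint on
both strands (the reverse complement of a direct-repeat run is again a
direct-repeat run), and a strand-consistency test confirms mirrored
coordinates on the reverse-complemented genome.

`dereplicate_repeats()` collapses exact and reverse-complement duplicate
repeats across genomes, keeps every contributing taxon, and assigns
deterministic zero-padded ids in (taxon, genome, position) order. Spacer
ids downstream are `repeatID-serial`, e.g. `01-103`.

### Read-level spacer mining

`extract_spacers()` anchors on the dereplicated repeats (those within
±12 nt of `approx_repeat_size = 36`). For each read it locates every
ungapped occurrence of the repeat on either strand with at most
`max_mismatch = 2` substitutions; the subsequence strictly between two
consecutive same-strand hits, with length inside the spacer bounds, is a
full spacer candidate, canonicalized to the repeat's orientation (so
minus-strand reads yield byte-identical catalogs). One-sided candidates
are counted as partials but never enter the catalog: their outer boundary
is unknowable. A candidate is retained when at least
`min_neighbor_support = 2` distinct reads produce it. We read the
neighbor-support threshold as *distinct supporting reads per
(repeat, spacer) pair*; this is the conservative, implementable reading
of a support-threshold on repeat-adjacent spacer observations, and it is
exposed as a parameter. Reverse-complement spacer pairs arising under
different repeats are deliberately kept as distinct records — they are
distinct immunological observations, and collapsing them would hide the
strand relationship between arrays.

Completeness on clean data follows from geometry: a spacer is minable
only from reads containing repeat–spacer–repeat in full (106 nt at the
default sizes), so with read length *R* and merged coverage *c* the
expected support is `c (R - 105) / R` — about 11.6 at 250-nt reads and
20× coverage, comfortably above the threshold of 2; at 150-nt reads the
same coverage yields 6 and the two-read threshold starts to fail
stochastically. The simulator therefore defaults to 250-nt reads, the
read length of the study design it emulates.

### Spacer-protospacer matching and host prediction

`match_spacers()` reports **every** ungapped, full-length placement of
each spacer on each phage, on either strand, with at most
`floor((1 - min_identity) L)` substitutions over the full spacer length
*L* (`min_identity = 0.80`). Identity is substitution-based over the
entire spacer — no local trimming, no gaps, no PAM requirement. A
reserved flag exists for a gapped mode but is off by default: a
full-length substitution criterion is reproducible and auditable, and the
exhaustive-scan oracle in the test suite checks it bit-for-bit. One
floating-point caveat: `(1 - 0.80) * 30` is fractionally below 6 in
binary arithmetic, so the bound is computed with a 1e-9 epsilon before
the floor.

`predict_hosts()` turns hits into per-phage host calls by majority of
hit-contributing taxa: ties give `"unassigned"` with an ambiguity flag, a
best taxon reaching only a single hit is flagged weak, and a runner-up
with at least half the best count flags ambiguity without changing the
call. These rules are the package's own deterministic formalization of
the informal practice of discounting single cross-taxon alignments when
another taxon contributes dozens.

### Coverage and abundance

`map_reads()` is deliberately simple: candidate placements come from an
exact `seed_k = 15`-mer lookup of the read's first k bases on each
strand, scored by substitution count over the whole read; the best
placement is kept if its mismatch rate is at most `max_mismatch_rate =
0.05`, with ties broken uniformly at random under a recorded seed.
Equally good placements — for example a read from a region present
identically in two genomes — are therefore split evenly in expectation,
which is the property the HGT coverage signal relies on. The cost of the
single-seed design is that a read whose first seed carries an error or a
variant allele can go unmapped (~2% at 0.5% error); abundance comparisons
are unaffected because the loss is unbiased across genomes. Users who
need a production aligner can import ungapped SAM via `read_sam()`.

`coverage_track()` maintains exact depth conservation (the depth vector
sums to the total aligned bases) and normalizes per-position depth by
total sample reads. `rpkm()` is the plain closed form
`mapped / (length/1000) / (total/1e6)`; `abundance_table()` applies it
per genome and sample, summing contig lengths and counts for binned
genomes (MAGs). The denominator is **total trimmed sample reads**, not
mapped reads: the sequencing depth of a sample is what varies between
samples, and using it keeps a genome's RPKM invariant under proportional
subsampling (tested at 50% with a 3-SE binomial tolerance).

### Variant density and protospacer diversification

`pileup()` and `call_variants()` implement the minimal per-position
model: a position is a variant when any non-reference base reaches
`min_alt_reads` supporting reads, all qualifying alternates listed. The
default `min_alt_reads = 1` mirrors the use of unfiltered variant lists
to maximize recovered variation. That default is the right *inventory*
setting but the wrong *rate-comparison* setting at moderate depth: at 30×
coverage with 0.5% sequencing error the chance of at least one erroneous
alternate read at a position is `1 - 0.995^30 ≈ 0.14`, an error floor of
~14 false variants per 100-bp window that pushes any targeted/background
ratio toward 1. Rate-recovery analyses in this package therefore call
variants at `min_alt_reads = 3`, where the error floor drops to ~0.05
per window while planted variants at 50% allele frequency are still
called with probability ≈ 1. The threshold is an argument, not a
constant.

`window_variant_counts()` tiles each genome with non-overlapping 100-bp
windows anchored at position 0 (the final short window is kept,
un-normalized), and `protospacer_enrichment()` compares the mean variant
count of windows overlapping any protospacer interval by ≥1 bp against
the remaining windows. Overlap-by-one is the minimal reading of
"CRISPR-targeted region"; a flank parameter is available. Note an
attenuation property: if the elevated-rate region is a 34-bp protospacer
inside a 100-bp window, the recoverable ratio is diluted toward
`(34 r + 66)/100` of the background; parameter-recovery tests therefore
plant window-aligned targets so the estimator's own bias is not
conflated with the dilution.

`protospacer_logo()` builds the position frequency matrix over an
interval from reads whose alignments span it entirely — partial overlaps
would systematically under-weight interval edges — and reports
per-column information content `2 − H` bits, with `H` the Shannon
entropy of the normalized column.

### HGT scanning

`detect_high_coverage()` segments a (lightly smoothed, 51-nt moving
average) coverage track at `fold = 3` times the median depth of the two
1-kb flanking windows, treating the genome as circular for flank
computation, dropping regions under 200 bp, and *flagging* — not
filtering — regions within one flank of the assembly origin as possible
circular-permutation artifacts (terminal redundancy of circularly
permuted packaging produces exactly this signal at the origin). The
smoothing width trades boundary precision (±~25 nt) against
fragmentation of genuinely elevated regions by Poisson dips; raw depth is
used for the reported medians.

`align_region_to_host()` and `compute_ani()` share one alignment core:
exact k-mer seeds extended along their diagonal with an X-drop rule at
+1/−1 match/mismatch scoring. For ANI, the query genome is cut into
consecutive 1020-bp fragments, each aligned to the subject (best hit,
either strand) and kept when identity ≥ 30% over ≥ 70% of the fragment
length; ANI is the mean identity of kept fragments, reported one-way
(a→b) with the direction recorded, since reciprocal averaging conventions
differ between implementations. Self-ANI is exactly 100 by construction.

`find_short_repeats()` enumerates **all maximal** ungapped repeat pairs
(direct and inverted) within length bounds and a mismatch budget, seeded
by the pigeonhole principle (any qualifying pair contains an exact run of
`ceil((min_len − mm)/(mm + 1))` bases) and enumerated per diagonal with
sentinel mismatch positions — equivalent to brute-force enumeration,
which the test suite verifies. `find_tirs()` specializes it to inward
facing inverted arms bracketing ≥ 500 bp, the insertion-sequence
geometry, ranked by arm length then mismatches. Because maximality is
defined under the mismatch budget, a planted 17-bp repeat may be reported
with a few extra budget-absorbed flanking bases; callers compare by
containment, not equality.

`frame_shift_report()` aligns donor ORF and host copy globally with
affine gaps (+1/−1, open 3, extend 1), reports single-base indels with
their 0-based position in the host copy, and the first in-frame stop of
the host copy translated in the donor's frame when it precedes the
donor's own stop — the frameshift-pseudogene signature. An insertion
inside a homopolymer run is locatable only up to that run; the simulator
therefore plants the inserted base different from both neighbours so
truth recovery is exact.

## The synthetic community

`community_config()` defaults encode the emulated study conditions:

| Parameter | Default | Why |
|---|---|---|
| hosts | 3 genomes, 40 kb | three dominant CRISPR-bearing taxa; 40 kb keeps desk-scale runtimes while being ≫ array and insert sizes |
| arrays per host | 2 × (10 spacers, repeat 36, spacer 34) | repeat size matches the mining anchor default; 60 spacers total |
| phages | 5 genomes, 25 kb | several phages per community, within the 20–60 kb range typical of tailed phages |
| samples | 3, hosts stable, phages variable (one phage absent from two samples) | host communities are conserved across aggregates while phage presence fluctuates |
| spacer provenance | 50% of spacers copied from the host's phages, 2 substitutions each | half the immune record points at the resident phages; mutations keep matches below identity 1 but above the 80% rule |
| HGT insert | 1044-bp donor ORF, 17-bp direct repeats, 1 phage-side repeat mismatch, insertion at offset 300 | lysin-sized gene; the repeat footprint and single-nucleotide insertion reproduce the transposon-mediated transfer signature |
| variants | phage-only, background ~0.17%/bp, 3× inside protospacers, allele frequency 0.5 | a "nearly threefold" diversification regime concentrated on CRISPR-targeted sequence |
| reads | 250 nt, 4000/sample, 0.2% error, constant Q35 | the 2×250 sequencing protocol scaled down; see the support-geometry argument above |

The generator plants arrays and the HGT insert by replacement at
non-overlapping positions (genome lengths stay exact), draws genome
backbones i.i.d. uniform over ACGT to avoid accidental repeat structure,
assigns each phage a true host round-robin, and emits a truth table
(array/repeat intervals, spacer provenance, variant positions, the full
HGT record, per-read origins). Reads are drawn with probability
proportional to abundance × length, uniform position and strand, planted
variants applied per read at their allele frequency, then i.i.d.
substitution errors; everything is deterministic given the seed.

What the simulator does *not* model — and what passing tests therefore do
not show about real data: indel sequencing errors and quality-score
structure (qualities are constant; trimming is tested on hand-built
reads), GC bias and non-uniform coverage, paired-end structure, repeat
families shared between taxa, degenerate repeat ends within one array,
assembly errors in the reference genomes, and gapped spacer-protospacer
alignments. The host-prediction completeness result in particular says
the chain is *internally lossless* under its own assumptions, not that
80%-identity ungapped matching recovers every host link in a real
metagenome.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory; GFF3/SAM are
  converted at serialization, BED stays 0-based. One convention, applied
  at boundaries only, prevents off-by-one drift.
* N bases: mapped to N on ingest (with a warning), counted as mismatches
  in every comparison, excluded from pileup base counts but included in
  depth.
* Ties: repeat-consensus columns break alphabetically; host-call ties
  return `"unassigned"`; mapper ties break uniformly under a recorded
  seed; spacer serials order by descending support then sequence.
* Degenerate inputs: empty FASTA → empty set; genomes without arrays →
  empty list; a catalog spacer absent from all phages simply yields no
  hits; an all-zero coverage track yields no regions; ANI with no passing
  fragment is flagged undefined rather than returning a number.
* The enrichment ratio with a zero background mean is flagged undefined
  (NA), never infinite.

## Problem sizes used by the tests and the acceptance script

Runtimes are kept desk-scale by construction: the mining/host-prediction
community is 3×40 kb hosts + 5×25 kb phages at ~20× merged host coverage
(12,000 × 250-nt reads); enrichment recovery uses a 50-kb genome at 30×
(10,000 × 150-nt reads) per ratio; the HGT scenario is one 40-kb host and
one 20-kb phage at 12:1 abundance (12,000 reads); ANI runs on 30-kb
genome pairs (30 fragments). These sizes give the statistical resolution
the assertions need (e.g. ~8% CV on the enrichment ratio against a 25%
band) at a few seconds to ~1 minute per scenario.

## Known limitations

* The spacer miner requires both flanking repeats inside one read; it
  cannot recover spacers at array termini next to a single repeat copy,
  nor from reads shorter than `2·repeat + spacer`.
* The mapper is ungapped and single-seeded; indel-bearing reads and reads
  with seed-region errors are unmapped by design.
* `detect_arrays()` reports the conserved repeat core, not leader-end
  orientation or CRISPR subtype; arrays with heavily degenerate terminal
  repeats will be truncated or split.
* ANI identity is measured on ungapped diagonal extensions; indel-rich
  genome pairs will under-cover fragments and the coverage filter, not
  the identity average, will carry the signal.
* Host prediction weighs spacer *counts*, not spacer abundances or
  match qualities beyond the identity threshold.
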