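---
title: "minitax: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{minitax: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minitax)
```

## The problem

Quality assessment and contamination screening of sequencing submissions
need a taxonomic profile of every run, computed fast enough to ride along
with routine processing.  minitax implements a MinHash-minimizer k-mer
toolchain for that purpose: it builds taxonomically merged 32-mer
databases from reference sequences, classifies reads ("spots" -- all
mates of one sequencing cluster) by exact k-mer matching with
lowest-common-ancestor (LCA) resolution, and removes host (human) reads
from FASTQ files against a subtraction database before data leave the
submitter.

## k-mer representation

A k-mer (k = 32 throughout; the parameter exists but every database
format fixes 32) is packed 2 bits per base into a 64-bit integer:
A = 00, C = 01, G = 10, T = 11, first base in the most significant bit
pair.  This particular bijection makes numeric order coincide with
lexicographic order of the sequence, which is convenient but not load
bearing; it is frozen and documented.  Because R has no native unsigned
64-bit type, packed k-mers cross the R boundary as fixed-width 16-digit
lowercase hex strings -- lexicographic order on the strings equals
numeric order on the values, so sorting, set operations and `match()`
behave exactly as they would on the integers.  All arithmetic happens in
C++.

Matching is strand-independent: every k-mer is replaced by its
*canonical* form, whichever of the k-mer and its reverse complement has
the lower 64-bit value.

## Minimizer selection

References are tiled with non-overlapping windows of W bases.  The
candidates of a window are the k-mers *starting* inside it, so each
window effectively extends k-1 bases to the right (its "wing"); the
final window is truncated by the sequence end but still contributes if
any candidate survives.  Every candidate is canonicalized and hashed
with 64-bit FNV-1 (offset basis 14695981039346656037, prime
1099511628211, multiply-then-XOR), and the candidate with the minimal
hash represents the window.  Numerical choices that the hash definition
leaves open are frozen as: the hash input is the 8 bytes of the packed
canonical k-mer in little-endian order; ties on the hash break to the
smaller canonical value, then the leftmost position.  K-mers containing
any non-ACGT base are skipped at build and query time alike.

Window sizes, roughly proportional to genome size:

| database | Viruses | Bacteria / Archaea | Eukaryota |
|----------|--------:|-------------------:|----------:|
| dense (`tree_filter`) | 64 | 64 | 64 |
| sparse (`tree_index`) | 64 | 2000 | 8000 |

The human scrubber database uses W = 32, twice as dense as the standard
databases, and the complete non-redundant k-mer set of a reference is
the special case W = 1.

A consequence of the wing worth knowing: the window partition of a
sequence and of its reverse complement only mirror each other exactly
when the length is W + k - 1 modulo W, so minimizer *sets* of the two
strands coincide only at such lengths (the globally minimal-hash k-mer
is selected on both strands at any length).  Queries are unaffected --
they enumerate every position.

## Database construction

Per taxon, the union of window minimizers over all its reference
sequences forms a deduplicated set.  Low-complexity k-mers are then
deleted: any 32-mer in which a single homopolymer run or a single
perfect dinucleotide tandem repeat (two distinct alternating bases,
length counted in bases) spans strictly more than 50% -- more than 16 of
32 bases -- is removed.  A run of exactly 16 is retained.  Filtering
runs *before* merging (the ordering is exposed as a switch); filtering
first avoids promoting low-complexity k-mers to interior nodes where
they would be harder to attribute.

Merging reassigns every k-mer to the LCA of all the taxa whose sets
contain it.  This is the unique consistent closure of "k-mers shared by
sibling species move up to the common parent": unique k-mers stay
diagnostic of their taxon, k-mers shared across super-kingdoms end at
the global root.  The contract is the per-k-mer LCA assignment, not a
traversal order, and the tests compare against a brute-force oracle.
The taxonomy comes from a two-column "parents" file (node, parent;
a node listed as its own parent is a root); a synthetic global root
(TaxId 1) joins the four super-kingdom roots, mirroring the NCBI
convention, so cross-kingdom LCAs are defined.

Serialization:

* **dbs** -- one 12-byte record per k-mer: 8-byte little-endian packed
  k-mer, 4-byte little-endian TaxId; records strictly sorted by k-mer.
* **dbss** -- the 8-byte k-mers only (33% smaller), grouped by ascending
  TaxId with each group sorted, plus a text annotation sidecar of
  `TaxId<TAB>count` lines whose cumulative sums are byte offsets.  This
  enables loading only selected TaxIds' k-mers.

## Query and resolution

No minimizer sampling is applied to queries: every position of every
read in a spot yields its canonical k-mer, the spot's set is
deduplicated, and each k-mer is looked up exactly.  Hits are reported
one line per spot with hits: the spot id, then TAB-separated `TaxId` or
`TaxIdxN` tokens in ascending TaxId order.  The format is a documented
dialect of this package (the concept, not the bytes, being fixed by the
upstream design); a parser is provided.

A spot resolves to a single taxon conservatively: among its hit TaxIds,
only the leaf-most (those with no other hit strictly below them) are
kept, and their LCA is the answer.  A coherent chain (species, genus,
class) resolves to the species; hits to two sibling species resolve to
their common parent.  Run-level reports aggregate resolved spots per
node with self counts, subtree totals, and self percentages of all
resolved spots.

The two-phase pipeline screens first against the sparse database,
resolves each spot, and accumulates per-species "biological read"
counts over each species' subtree (strain-level resolutions count
toward their species; phase 1 resolves spots rather than counting raw
hits -- a documented choice where either reading is defensible).  A
species is selected when its count exceeds 100 (Eukaryota), exceeds 10
(Bacteria, Archaea), or reaches 1 (Viruses; the stated sensitivity is
1--2 reads and the most sensitive reading is the default, configurable
via `screen_thresholds()`).  The selection is expanded to each selected
taxon's subtree (regaining strain k-mers) plus its ancestors (merged
k-mers live at interior nodes), minus explicit exclusions, and only
those TaxIds' dense k-mers are loaded for the quantitative second pass.

## Host-read scrubbing

The subtraction database is a single-TaxId dense build (W = 32) of host
references with *no* merging, the low-complexity filter applied, and
any k-mer also present in the merged Bacteria and Viruses kingdom
databases subtracted, protecting clinical-pathogen signal.  A spot is
removed when at least `min_hits` of its query k-mers match; the default
1 is the aggressive setting appropriate for privacy scrubbing and is a
documented choice (the upstream criterion is not published).  Removal
is all-or-nothing across mates, retained records are copied
byte-identically in input order, and removal -- not masking -- is the
only supported action.

## The synthetic world

`simulate_world()` generates the fixture ecosystem every test uses: a
taxonomy of a global root, real super-kingdom root TaxIds (so window
sizes and thresholds resolve unchanged), genera, and species leaves;
each genus has a random ancestral genome and its species' genomes
diverge from it by independent per-base substitution, so siblings share
k-mers and exercise merging.  `simulate_reads()` draws uniform start
positions, random strand, and independent substitution errors -- no
indels, no quality model, intentionally simpler than a full read
simulator.  Consequences for interpretation: passing tests demonstrate
the combinatorial correctness of the toolchain (encoding, selection,
merging, lookup, resolution, thresholds) and its behavior under
substitution noise; they say nothing about indel-rich platforms,
real-genome repeat structure, uneven coverage, or RefSeq-scale database
composition.  Strain-exclusion accuracy at published scale is
explicitly out of reach on synthetic data; the accuracy *metrics*
(Sensitivity = TP/(TP+VP+FN+FP), PPV = TP/(TP+FP), Recall = TP/(TP+FN),
F1 = 2·PPV·Recall/(PPV+Recall), with "vague positives" being
correct-but-higher-rank calls) are implemented and oracle-tested.

A sibling effect worth naming: a k-mer present in both sibling genomes
may be *sampled* (as a window minimizer) from only one of them, leaving
it diagnostic of that sibling rather than merged to the genus.  An
error-free read from the other sibling can then legitimately resolve to
its sister species -- inside the correct genus, never to an unrelated
branch.  At 2% sibling divergence this affects roughly 2--3% of reads
in the recovery experiment; the end-to-end tests assert >= 95% of
classified reads resolve within the true lineage and that no read
leaves the true genus at error 0.

## Problem sizes and degenerate inputs

The test and verification workloads are sized for interactive runs: the
recovery experiment uses 5 genera x 2 species of 100-kb genomes with
1000 100-bp reads per species at 0.2% error; scrubbing mixtures use two
100-kb genomes with 1000 reads each; database-constant checks use one
6.4-Mb (dense), 8-Mb (eukaryotic sparse), 2-Mb (bacterial sparse) and
320-kb (scrubber) random sequence.  Degenerate inputs have defined
behavior: sequences shorter than k contribute nothing; an all-ambiguous
window is absent; an empty database file is valid and empty; a dbs file
whose size is not a multiple of 12, or with unsorted records, is
rejected as corrupt; an empty tax_list in dbss query mode is an error;
a scrub database left empty after subtraction is an error; all-zero
confusion counts yield undefined (NA) metrics rather than exceptions,
with F1 guarded to 0 when TP = 0 but reads were classified.

## Limitations

* k is parameterized but only k = 32 is exercised; the binary formats
  assume 8-byte k-mers.
* Classification percentages are not normalized by genome size; that
  interpretation burden stays with the user.
* The hits-file dialect is byte-stable within this package but is not a
  claim of byte compatibility with any other tool.
* Phase-1 screening is qualitative by design; species below their
  read-count thresholds are invisible to the second pass unless a
  relative is selected.
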