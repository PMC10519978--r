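---
title: "Composite-motif DNA storage: model, simulators and the Motif-Search decoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-motif DNA storage: model, simulators and the Motif-Search decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifstore)
```

## The storage model

Conventional DNA storage writes data base by base: four repeating units per
synthesis cycle, hence at most 2 bits per cycle. This package implements a
motif-based alternative in which the repeating unit is a prefabricated
25-nt *motif* drawn from a fixed library, and a position of an oligo is
occupied not by one motif but by a *composite motif*: an unordered k-subset
of the m payload motifs, physically realized by mixing k motifs in one
ligation reaction so that different molecules of the same oligo carry
different members. A composite position can take C(m, k) values and
therefore stores

    floor(log2 C(m, k))  bits per synthesis cycle,

84 bits for the default m = 96, k = 32 — against 6 bits per cycle had the
same 96 motifs been used one at a time, and 2 bits for base-by-base
synthesis. Physical density is bits per cycle divided by the motif length
(84/25 = 3.36 bits/nt at the defaults). The library also carries a small
set of *address* motifs that index *logical sequences* (an address plus an
ordered list of composites), and a single constant *spacer* motif placed
before every payload motif. The spacer is what makes one universal bridge
oligo sufficient for enzymatic assembly, and it doubles as the decoder's
segmentation anchor.

### The value-to-combination bijection

The mapping between a bit chunk and a k-subset must be a bijection fixed
for the life of the archive. We use the *colexicographic combinadic*: the
r-th k-subset `{c_1 < ... < c_k}` in colex order satisfies

    r = sum_i C(c_i, i),

which gives a closed-form rank and an O(mk) unrank. Value 0 maps to
`{0, 1, ..., k-1}` (for the toy 7-motif, k = 2 scheme: bits `0000` map to
payload motifs 0 and 1). Colex was chosen over lexicographic order because
its rank formula indexes members directly by their own value, independent
of m; the choice is documented here as the on-disk canonical order. Only
the first 2^84 of the ~3e25 subsets are ever emitted; ranks above the bit
capacity are unused by construction.

All combinatorics are computed exactly: binomial coefficients come from a
Pascal-triangle cache of arbitrary-precision integers (base-2^24 limbs in
doubles, every intermediate below 2^53), and bit capacities from integer
bit length. No floating-point logarithm or binomial approximation
participates in any ranking path, so encodings are bit-identical across
platforms.

### Framing

Payload bits are consumed MSB-first within each byte, split into chunks of
`bits_per_composite`; the final chunk is zero-padded at the tail and the
true byte length is recorded in a JSON manifest. Blocks of
`positions_per_oligo` composites are assigned sequential address indices
(single-tier addressing; data larger than the address space is an error,
not silently re-tiered). A `replicate_addresses` flag stores the same
block on every address — the layout used to stress the read pipeline, where
one 10-byte message becomes 8 x 32 = 256 distinct molecules. No
error-correcting code is layered on top: the design question under study
is whether consensus alone recovers the data.

## What the simulators emulate

**Assembly (`expand_pool`).** Cartesian mode enumerates every per-position
choice of one member motif — the product over positions of k molecules per
logical sequence — which guarantees every member is physically present
(the property the decoder's coverage analysis assumes). Sampled mode draws
a finite number of molecules with uniform per-position choices, modeling
stochastic ligation; it exists to stress the decoder with member dropout,
and is not the default. The molecule layout is
`address + spacer + payload_1 + spacer + payload_2 + ...`; bridge oligos
direct the ligation chemistry but do not appear in the product strand, so
they are not modeled as sequences.

**Sequencing (`simulate_reads`).** Direct nanopore sequencing of sub-200-nt
oligos produces a characteristic error structure, which the channel model
reproduces artifact by artifact:

* mixed per-base errors with no dominant type — defaults
  `p_sub = p_ins = p_del = 0.033` (about 10% total). These magnitudes are
  calibration choices of the simulator standing in roughly an order of
  magnitude above array-synthesis channels, not measured values;
* heavy end truncation, worse at the 3' end (`p_clip3 = 0.3`, mean 8 nt,
  versus `p_clip5 = 0.1`, mean 4 nt), emulating soft-clip-like signal loss;
* merged reads: with `p_merge = 0.5` a read continues into another molecule
  (geometric, mean 2 molecules/read), emulating mis-segmented squiggles
  that concatenate strands without any linker sequence;
* junk reads (`p_junk = 0.05`): random sequence with no provenance,
  emulating empty signal basecalled as a read;
* unbiased strand flips per molecule (`p_revcomp = 0.5`).

*Coverage semantics.* `coverage` is the expected number of reads covering
each distinct molecule: every molecule is sequenced Poisson(coverage x
copies) times and the instances are then grouped into (possibly merged)
reads. The read count is therefore about `coverage x pool x (1 - p_merge)`,
not `coverage x pool`; the per-oligo Poisson law is the invariant we keep,
because it is what "n-fold coverage" means for recovery analysis and
subsampling.

Ground truth (provenance intervals per read, per-instance error events) is
carried alongside the reads, so realized error rates are measured by
counting — `channel_stats()` — rather than re-aligning. What the simulator
does *not* reproduce: signal-space (squiggle) artifacts, basecaller-specific
error correlations, context-dependent error hotspots, and real clip-length
distributions. Passing the simulated acceptance conditions therefore shows
the decoder tolerates this error *structure* at these rates; it is not a
claim about any particular flowcell.

## The Motif-Search decoder

Inference runs per read, on the read and its reverse complement, in three
stages.

**Segmentation.** All spacer 4-mers (2-bit encoded) index the spacer; every
read 4-mer that hits the index votes for the normalized start `p - offset`.
Positions with fewer than `ceil(spacer_length / k) = 7` votes are dropped
(a clean 25-nt spacer accrues 22), surviving neighbours within ±3 nt merge
to a vote-weighted centroid (indels fragment votes across adjacent
positions), and each candidate is refined over shifts in ±3 nt by a CGK
randomized embedding: query window and spacer are embedded with shared
seeded random bits (3 repetitions) and compared by Hamming distance, a
cheap surrogate for edit distance whose agreement with the exact-edit
argmin is itself a tested property. The embedding construction is our
choice of randomized edit-to-Hamming embedding; repetitions and shift
window are configurable. Candidates are then chained: an oligo with M
motifs has M-1 spacers spaced `d = motif_length + spacer_length` apart, so
chains are all runs of candidates with consecutive gaps within ±5 nt of d
(single-spacer oligos degenerate to singleton chains).

**Mapping.** The windows implied by a chain — address before the first
spacer, payloads after each spacer, widened ±4 nt for indels — are aligned
against every candidate motif of the matching role with an affine-gap
local aligner (integer scores; match +2, mismatch -4, gap open 4, extend
2; a length-L gap costs 4 + 2L). The argmax motif is called (ties to the
lower index); any call below 0.6 x the perfect score (30 of 50 for
25-mers, i.e. roughly 3+ edits of slack) rejects the chain. The aligner is
implemented in C++ for throughput and is cross-checked in the tests against
an independent alignment implementation and against brute-force
edit-distance calls.

**Overlap check.** Each read nucleotide may support one oligo only. Chains
are kept greedily by descending mapping score (ties: leftmost, then fewer
positions) if their span overlaps no kept chain. Ownership spans exclude
the ±4 alignment margin, so molecules that abut in a merged read do not
mask each other. Greedy selection follows the decoding contract and is not
an exact maximum-weight interval schedule; the tests document an instance
where the two differ. Orientation is decided per read by the higher summed
kept-chain score — a whole-read choice, so the minority strand of a
mixed-orientation merged read is sacrificed; this is the main structural
loss of the decoder and the reason complete recovery needs roughly 20x
rather than 5-10x coverage.

**Consensus.** Inferred oligos are grouped by address motif; at each
payload position motifs are ranked by support count (ties: higher summed
alignment score, then lower index) and the top k with support >= 2 form the
recovered composite. An address that cannot field k supported motifs at
some position is flagged failed rather than guessed. Positions are indexed
ordinally per inferred oligo; aligning positions across oligos of different
inferred lengths is not attempted (with the default single-position layout
the question does not arise). The recovered composites are ranked back to
bit chunks and the manifest strips the padding.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open; motif indices are FASTA record
  order, 0-based, everywhere.
* Vote threshold `ceil(spacer_length/k)`: the strict reading of "fewer
  than spacer_length/k votes" when the ratio is fractional.
* Refinement ties prefer the smaller |shift|, then the negative one;
  windows clamped at read edges are flagged and resolved by mapping.
* Empty windows (a chain pressed against a read end) reject the chain with
  a reason rather than erroring.
* The spacer splits 13 nt (5') / 12 nt (3') around each payload in its
  synthesis form; for other spacer lengths the split is ceil/floor of
  half, keeping concatenated forms spacer-complete.
* `generate_library` uses greedy rejection sampling under a minimum
  pairwise edit distance (default 9 for 25-mers, the separation that keeps
  mapping unambiguous at the channel's error rates; real libraries from
  published barcode sets can be loaded instead, and their realized
  separation is a measured property, `min_pairwise_distance()`, not an
  assumption). Infeasible requests (e.g. five 6-mers at distance >= 5)
  fail after a bounded attempt count with a report of how many motifs were
  found.

## Scale of the shipped analyses

The test-suite and acceptance analyses run the full experimental geometry
(8 x 96 library, k = 32, 256 molecules) with the default channel over
coverage grids up to 30x and five simulation seeds, plus a reduced-scale
expanded-space study (64 x 256 reference space at 27x, one seed) for
false-positive behaviour. These sizes were chosen so the complete analysis
reruns in minutes on a laptop while keeping every per-oligo support count
in the regime where the consensus thresholds bind; the recovery-coverage
relationship itself is computed fresh on every run by
`scripts/acceptance.R`.

## Known limitations

* Hierarchical/multi-motif addressing is not implemented; data larger than
  the address space is an error.
* The expanded-space FP study extends a generated library; it does not
  model the correlated similarity structure of a real barcode catalogue.
* Consensus assumes the address call is reliable enough to cluster on;
  address-free clustering by sequence similarity is out of scope.
* The channel model treats errors as i.i.d. per base; real nanopore errors
  are context-correlated, so real-data recovery curves may sit above or
  below the simulated ones at equal nominal rates.
* Wet-lab concerns — spacer/bridge thermodynamics, ligation efficiency,
  phosphorylation — are outside the model; the simulators start from the
  assembled molecule.
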