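---
title: "Reconstructing germline chromothripsis from long-read split alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing germline chromothripsis from long-read split alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thripsis)
```

## The problem

Chromothripsis shatters one or a few chromosome regions into fragments that
rejoin in essentially random order and orientation. When it happens in the
germline it can produce a karyotypically "balanced" translocation that in
fact hides many breakpoints, inversions and deletions — and therefore a
phenotype that no single breakpoint explains. Short reads rarely span more
than one breakpoint, and microarrays only see dosage. Long reads change the
game: a single molecule of 10 kb or more can cross several junctions, so the
order and orientation of fragments becomes directly observable.

`thripsis` implements the inference chain needed to go from long-read split
alignments to a complete derivative-chromosome reconstruction:

1. **Chains and junctions** — per-read segment chains are read from PAF or
   MAF; each non-colinear adjacent segment pair defines a rearrangement
   junction between two oriented breakends.
2. **Grouping** — reads sharing a junction (within a tolerance) are clustered
   into rearrangement groups.
3. **Control subtraction** — groups whose junctions recur in any control
   individual are discarded; what survives is patient-only.
4. **Consensus** — each surviving group is merged into one breakpoint-level
   consensus rearrangement (ordered, oriented reference segments with
   consensus junction coordinates).
5. **Linking** — consensus rearrangements are ordered and oriented into
   derivative chromosomes by matching their open ends, with an explicit
   uniqueness check.
6. **Inference and annotation** — deletions fall out of the reconstruction as
   uncovered interior intervals; gene impact and relative expression
   (delta-delta-Ct) annotate the result.

A first-class synthetic-data module generates toy genomes, planted
rearrangement plans, simulated reads and control cohorts with full ground
truth, so each stage and the whole chain are testable without any external
data.

## Breakend conventions

A junction joins two breakends, each `(chromosome, position, side)`. The
`side` records where the retained reference sequence lies relative to the
position: `head` means the segment ends at this position coming from smaller
coordinates (a forward segment's right edge, or a reverse segment's right
edge in traversal terms); `tail` means the segment continues toward larger
coordinates. Concretely, for two adjacent segments in a read, a forward left
segment contributes `(chrom, ref_end, head)`; a reverse left segment
`(chrom, ref_start, tail)`; symmetric on the right. Junctions are stored
both in read-traversal frame and in a canonical frame (breakends sorted
lexicographically), so the same junction observed from reads in opposite
orientations compares equal.

Colinearity is judged with a gap tolerance: two adjacent segments on the
same chromosome and strand whose reference advance matches their read
advance within `colinear_gap_tol` are one alignment split by noise, not a
junction. A corollary worth stating: any rearrangement whose reference
displacement is below this tolerance (for example a repeat expansion by less
than ~1 kb) is invisible at the junction level. This bounds from below any
size threshold applied to loop-type events (see classification below).

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `min_seg_len` | 200 | bp | minimum aligned segment length on the read |
| `max_overlap` | 50 | bp | tolerated read-coordinate overlap between chained segments |
| `colinear_gap_tol` | 1000 | bp | colinearity tolerance (absorbs nanopore indel noise) |
| `match_tol` | 200 / 1000 | bp | breakend matching tolerance; presets `error_free` / `noisy` |
| `min_reads` | 3 | reads | minimum support per group |
| `gap_min` | 10000 | bp | forward gap above which a junction is a `long_gap` |
| `insert_min` | 300 | bp | read gap above which a junction is an `unaligned_insert` |
| `unit_threshold` | 5000 | bp | loop span separating tandem multiplications from repeat expansions |
| `min_size` (deletions) | 10000 | bp | minimum inferred deletion |

The two `match_tol` presets reflect the two simulation regimes: exact chains
need only a symbolic tolerance, while 5% base error produces breakpoint
estimates tens of bases off. `unit_threshold` was placed at 5 kb rather than
at a repeat-unit-sized value because loops smaller than `colinear_gap_tol`
never surface as junctions at all; a 500 bp threshold would define an empty
category.

## Consensus at breakpoint level

The consensus step deliberately works at coordinate level, not base level.
The linking stage needs only junction coordinates, segment order and
orientation, so the consensus of a group is computed as:

- junction clusters at `match_tol`, with the **lower median** of member
  breakend positions as the consensus coordinate (robust to endpoint wobble;
  ties break toward the smaller coordinate for determinism);
- a junction-adjacency path assembled from the members' traversal orders,
  after folding reads that traverse the event in opposite directions into a
  common frame;
- outer segment extents taken as the maximal reach of any member read.

Groups whose members imply a branched or cyclic junction order, or disagree
on orientation after reorientation, are emitted to an `unresolved` report
rather than guessed. Duplicate events discovered in both orientations are
removed by traversal-frame comparison (`traversal_frames_equal`), which
treats a consensus and its full reversal as the same event.

## Linking into derivative chromosomes

Every consensus rearrangement has exactly two *open ends*: the
reference-facing flanks of its outermost segments, each with an extension
direction along the reference. Two open ends are a *link candidate* when
they lie on the same chromosome facing each other and no third group's
breakend lies strictly between them (an end positioned exactly on a breakend
is not blocked; the case is degenerate in practice). An end with a free run
to a chromosome terminus is terminus-capable.

Linking selects a perfect matching: every end either linked to exactly one
candidate or assigned a terminus (each terminus used at most once), such
that the group graph decomposes into simple paths. The search is a
backtracking enumeration; the package insists that **exactly one** valid
matching exists. Zero matchings raise an "inconsistent rearrangement" error,
several raise an "ambiguous" error — alternatives are enumerable via
`link(..., enumerate = TRUE)` but never chosen silently. This mirrors the
scientific claim such a reconstruction must support: the derivative
structure is only reportable because no other arrangement fits the data.
The test suite checks the search against an independent brute-force
enumeration of all end-pairings for consensus sets of up to eight groups.

Paths are then flattened into maximal breakpoint-to-breakpoint fragments by
merging colinear neighbours, and deletions are the uncovered reference
intervals interior to the covered span (terminal gaps are incompleteness,
not deletions). A deliberately simple model restriction: fragments claimed
by two different consensuses indicate more than one rearranged allele and
are an error — the package models a single germline rearranged allele.
Chromosome arms and centromeres are ignored; derivative termini extend to
toy-chromosome ends, and the acentric/dicentric question is out of scope.

## What the simulator emulates — and what it does not

`simulate_reads` draws read lengths from a log-normal (mean 11,451 bp by
default, matching a realistic nanopore run) truncated to
`[500, min(length_max, sequence length)]`, with uniform start positions on
each derivative and reads from both strands. The upper truncation
(`length_max`, default 100 kb) encodes the practical bound on read length;
it also guarantees that on plans whose full-size fragments exceed it, no
single read spans a whole fragment, which keeps the read-group structure
deterministic.

With error rates zero the emitted chains are the exact reference segment
chains of each read — an error-free alignment oracle. With nonzero rates the
package does not re-align bases (alignment is consumed, not produced);
instead it models what errors do to an aligner's output: at every junction
the read cut point is ambiguous, so it shifts by a rounded normal deviate
(sd `600 x total error rate`, i.e. ~30 bp at 5%) shared by the two flanking
segments. Base-level errors are applied only when FASTQ output is requested.
Only the rearranged haplotype is simulated: reference-allele reads of a
heterozygous carrier contain no junctions and are discarded by detection
anyway.

Features of real data deliberately not emulated: repeats and segmental
duplications (toy genomes are uniform random sequence, so mapping ambiguity
does not exist here), chimeric/adapter artifacts, coverage bias, and
base-caller error structure. Passing tests therefore demonstrate the
correctness of the inference chain given split alignments, not robustness to
mapping ambiguity in repetitive genomes.

## The canonical fixture

`chromothripsis_fixture` plants a two-chromosome germline chromothripsis with
interchromosomal exchange on 12 Mb and 6 Mb toy stand-ins for the two
partner chromosomes: 19 fragments (15 from the chr8 analog, 4 from the
chr18 analog, ids 6, 7, 14, 15), derivative A carrying fragments 1–14 and
derivative B fragments 15–19, five reverse-oriented fragments, and interior
uncovered gaps of exactly 456, 1957, 520 and 3529 kb (chr8 analog) and
1528 kb (chr18 analog). Deletion sizes are kept at real scale even though
the chromosomes are scaled down, so size recovery is meaningful.

Three fragments are tiny (6, 9 and 8 kb; two of them adjacent in derivative
A). Reads longer than these fragments span both flanking junctions, so the
17 derivative adjacencies collapse into 14 read groups — the linking stage
receives 14 consensus rearrangements and must place all of them, uniquely,
into two derivative paths. The true breakpoint coordinates of any real case
are not modelled; only deletion sizes, fragment counts and
chromosome-of-origin assignments are meaningful, and the orientation vector
is a documented constant of the fixture.

Problem sizes used by the shipped test suite, chosen to exercise every
stage at desk scale: the fixture at x20 coverage (~17,500 reads); 200
random plans (2–10 fragments per derivative, fragments 120–260 kb) at x16
coverage with 9 kb mean reads for exact-recovery testing; 200 random
consensus sets of up to 8 groups for the linking oracle; 33-control cohorts
for filter behaviour.

## Numerical and degenerate-input choices

- All generators draw from named, seeded RNG streams isolated from the
  global RNG; identical seeds give byte-identical output.
- Lower median for consensus coordinates; deterministic path-direction
  choice (the endpoint with the lexicographically smaller breakend starts).
- Touching fragments (zero-length gap) produce two breakends at one
  coordinate with opposite sides; matching requires identical sides, so they
  never merge.
- Empty inputs: empty chain tables, empty junction sets and empty cohorts
  flow through and yield empty (not invalid) results; reports render
  whatever stages exist and list the missing ones.
- Micro-homology at junctions (reference overlap of adjacent segments up to
  ~100 bp) does not break junction calling; the breakend position is taken
  from the left segment of the traversal, a documented asymmetry.

## Known limitations

- No copy-number estimation from read depth, and no phasing; a multiplied
  fragment inside a derivative would need depth evidence this model does not
  use.
- The single-allele assumption above.
- Element classification matches inserted sequence against a small consensus
  library with a local aligner; it stands in for genome-wide repeat
  annotation and is only as good as the library.
- Real-data group counts (how many patient-only groups a genome yields)
  depend on the individual and the cohort; the package reproduces the
  *mechanics* of that filter, not any particular count.
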