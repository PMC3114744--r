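---
title: "Meta-alignment: partitioning large alignment problems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-alignment: partitioning large alignment problems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalign)
```

## The problem

A global multiple sequence alignment problem can be large in two ways:
long sequences, or many sequences. Most aligners scale poorly in both
directions, and the better statistical models tend to scale worst. The
approach taken here is *meta-alignment*: the package never aligns anything
interesting itself — it partitions the problem so that an existing aligner
(the pluggable *backend*) is only ever asked small questions, and it
reassembles the answers. Partitioning is designed so that most
sub-problems are mutually independent and can run concurrently.

## Length-wise partitioning

### Constraints and the partial order

The input beyond the sequences is a set of *constraints*: pairs of base
positions, one in each of two sequences, asserted to be aligned. Such a
sparse alignment induces a partial order ≺ on all residue positions:
aligned positions are equal, and positions along one sequence increase.
Internally, equality classes come from union–find over the constrained
positions, and order queries use a threshold propagation that exploits the
structure of the poset: the upward closure of a position intersected with
any one sequence is always a suffix of that sequence, so a closure is just
one integer per sequence. `check_consistency` requires that no class holds
two positions of one sequence and that the class graph (classes linked by
within-sequence adjacency) is acyclic, delegating the cycle check to
igraph.

### Separations, cores, blocks

Given a consistent constraint set and an anchor position x,
`find_separation` computes per sequence the half-open interval from the
first position *not strictly below* x to one past the least position aᵢ
with x ≼ aᵢ. Everything left of the interval strictly precedes x;
everything at-or-right of its end strictly follows x. Consequently nothing
left of a separation can be aligned past its right edge without
contradicting the constraints, and when x is a fully aligned column the
separation is exactly that column (width 1 in every sequence). A sequence
with no position comparable to x has its interval extended to the sequence
end: nothing bounds where its residues may align, so they must all travel
with the ambiguous region. This per-sequence interval formulation is used
instead of materializing a single "rightmost" bounding position, which
need not exist in a general partial order; every guarantee is stated and
tested on the intervals directly.

`tile_blocks` paces anchors along the first input sequence (the
*reference* — the choice is arbitrary and fixed for determinism),
advancing `core_size` residues past the previous separation's end each
time. The region between two consecutive separations is a *core*; a
*block* is a core plus its flanking separations, and adjacent blocks
overlap in exactly the shared separation. If the constraints are a subset
of the true alignment, truth columns left of a separation have column
index at most that of the anchor and columns right of it strictly greater,
so no truly homologous pair spans two cores — the property the test suite
asserts on simulated instances.

Two practical rules close the gaps in this picture:

- **Truncation.** A block wider than `max_block_size` in some sequence is
  cut at exactly that width there; the cut sequence becomes part of the
  next block and that boundary carries *no* separation, so the
  independence guarantee is void across it (unavoidable: with no nearby
  constraints there is no sound cut point). The last block absorbs all
  remainders.
- **Clamping.** A separation computed from a later anchor can reach left
  of the previous separation's end for sequences the anchor knows little
  about; intervals are clamped so separations never overlap and cores
  never go negative.

### The block pipeline

`crumble_align` runs: tile → align each block with the backend (parallel
child jobs) → trim each shared separation off both adjacent block
alignments (masking by residue count, then dropping empty columns) →
realign each separation's pooled residues (parallel again; sub-problems
with at most one non-empty sequence skip the backend) → concatenate cores
and separations in order. Every residue of every input appears exactly
once, in order, in the output — the *projection* invariant enforced on
every backend result and asserted across a 50-seed randomized suite. With
`core_size` at least the total length the pipeline collapses to a single
backend call and returns its alignment bit-exactly.

## Depth-wise partitioning

### The stage-minimizing decomposition

Given a rooted binary phylogeny, `min_stage_decomposition` cuts it into
sub-trees that overlap at cut nodes. A sub-tree problem sees its
*frontier*: the leaf sequences of its region plus the inferred root
sequences of the sub-trees below it. Problems of one *stage* are mutually
independent; stages are sequential because a parent needs its children's
inferred roots. The dynamic program tracks A(i, j), the minimum stage
count for the clade of node i to present j sequences upward: leaves
present one sequence at stage 1 (extracting a sequence is itself counted
as a stage); for j ≥ 2 the j sequences split over the two children; and
presenting one sequence from an internal node means rooting a sub-tree
there, at one stage more than the best split of at most M sequences over
its children. The answer is A(root, 1). Ties break toward the smallest
left share, making the decomposition deterministic. The recurrence's
correctness is anchored to a brute-force oracle that enumerates *all*
decompositions (every subset of internal nodes as cut set) for every tree
shape up to seven leaves and for random larger trees; the two agree
exactly, and the stage count is non-increasing in M.

Note one convention: the trivial single-leaf "alignment" counts as a
visible stage, so a cherry under M = 2 has stage count 2. The enumeration
oracle shares the convention, so the optimality statement is
convention-free.

### Root inference and merging

Two inference methods are provided. *Maximal* assigns every alignment
column its most frequent non-gap base (ties A < C < G < T < N), giving the
longest root sequence that fits the alignment — one residue per column, so
its guide map is a bijection onto columns. It is biologically naive but
gives parents maximal opportunity to align homologous positions, and it is
the default. *Nearest-leaf* propagates the sequence of the sub-tree's
closest leaf (by branch-length distance, ties by leaf name); its guide map
hits only the columns where that leaf has residues.

`merge_alignments` splices children under a parent along these guide maps:
each parent column pulls the mapped child column; where a guide row is
gapped its child rows receive gaps; child columns never hit by a guide are
inserted immediately before the next mapped column (or appended). Guide
rows are then removed. The merge is validated against a naive column
expansion oracle, and composition of maps through nested merges lets the
final bottom-up merge run after all stages complete.

Out-groups: optionally each sub-tree problem also aligns the leaf outside
the sub-tree closest to its root (branch-length distance, ties by name)
for context; the out-group row is dropped afterwards and does not count
toward M (it is context, not content).

### Reduction to progressive alignment

With M = 2, nearest-leaf inference, no out-groups, and serial execution
the procedure *is* progressive alignment, and the package keeps this
reduction bit-exact. That constrains the built-in aligner's design: the
built-in progressive aligner represents every sub-alignment by its nearest
leaf, aligns the two representative sequences with optimal affine-gap
pairwise DP (Gotoh; gap of length L costs open + (L−1)·extend; traceback
prefers diagonal, then up, then left), and splices the children under that
pairwise alignment — leaf sequences guide every merge, exactly as the
depth-wise procedure does with nearest-leaf inference. A sum-of-pairs
profile–profile merge was considered and rejected: it cannot be
bit-identical to the sub-tree pipeline, whose sub-problems see inferred
root *sequences*, not profiles. Sequence-guided merging is a recognized
progressive variant and makes the equivalence a meaningful end-to-end
check of the decomposition, scheduling, inference and merge machinery
against a one-screen recursive implementation.

Default scores are match 1, mismatch −1, open −2, extend −1 — an ordinary
DNA parameterization, not tuned to anything. Without a guide tree one is
built by neighbor joining (ape) on a normalized shared 6-mer distance.

## The executor

Both pipelines express their work as a dynamic job hierarchy: a job's
action may create child jobs and a follow-on job that runs only after the
job and all its descendants succeed (the follow-on receives the children's
values and may spawn further children — so a sub-tree job can spawn block
jobs). Serial mode runs everything in order in-process; parallel mode runs
same-level children on forked workers (`parallel::mclapply`), collecting
results in child order so outputs are bit-identical across modes and
worker counts — asserted for both pipelines and their composition. The
original design this mirrors handed jobs to cluster batch systems through
on-disk files; here the transport is an in-process queue and the contract
(ordering, failure with ancestry reporting, cleanup ownership via each
job's temporary directory) is what is preserved.

## Scoring

The *average agreement* score projects both alignments onto each species
pair as an event list — residue i of X to residue j of Y, residue to gap,
gap to residue, columns gapped in both dropped — and counts the fraction
of the predicted projection's events present in the truth projection,
averaged over pairs (or a seeded sample of pairs, without replacement, for
very deep problems). The denominator is deliberately the *predicted*
event count, so the measure is asymmetric; identical alignments score
exactly 1 and alignments sharing no event exactly 0. Gap–gap columns are
excluded throughout, a convention the pairwise projection fixes once.

## The simulator

The generator exists so every algorithm is exercisable against a known
truth without external tools, and its defaults are the package's stated
study conditions. Topologies grow by a Yule process (uniform leaf splits);
branch lengths are exponential, rescaled to a prescribed total tree length
— 1.13 substitutions/site is used for the nine-species block-partitioning
instances, matching the divergence regime the method targets.
Substitutions follow HKY (default κ = 2, frequencies A/T 0.3, C/G 0.2)
through the matrix exponential of the normalized rate matrix
(`Matrix::expm`; the closed-form HKY solution serves as the independent
oracle in tests, and empirical transition:transversion counts at 50 kb
match it within three standard errors). Indels arrive as Poisson counts
per branch (default 0.02 events/site/unit length for each of insertion and
deletion — a realistic neutral-DNA order of magnitude), geometric lengths
(p = 0.4, mean 2.5), placed uniformly, deletions truncated at ends;
insertion and deletion conventions are the package's own, documented
choices. Homology is tracked by unique residue identities with interval
sort keys, so the truth alignment is exact: inserted residues are
homologous to nothing outside their sub-tree. The simulator deliberately
omits features of real genomes — retrotransposon insertions, rate
heterogeneity, rearrangements, base composition drift — so green tests
demonstrate algorithmic correctness under neutral evolution, not accuracy
on real genomic data.

The anchor constraint generator (unique exact k-mer matches per pair,
chained by longest increasing subsequence, greedily reconciled globally)
is likewise an admitted stand-in for a real constraint system such as a
pair-HMM anchor pipeline; constraints sampled from the simulator's truth
alignment are what the soundness guarantees are tested against.

## Numerical and degenerate-input choices

- Coordinates are 0-based with half-open intervals everywhere internally;
  MAF conventions are applied only in the writer.
- All tie-breaks are fixed and documented: consensus bases A < C < G < T
  < N; nearest leaves and out-groups by distance then name; DP splits by
  smallest left share; alignment traceback diagonal/up/left.
- Empty sub-problems: zero-length sequences are dropped from blocks;
  realignment sub-problems with at most one non-empty sequence bypass the
  backend; an empty input yields an empty alignment.
- Non-binary trees are rejected rather than resolved (resolve polytomies
  upstream, e.g. `ape::multi2di`); the decomposition recurrence is defined
  on left/right children only.
- A leaf may not be named `node<digits>`: those labels are reserved for
  inferred root rows.

## Problem sizes in the test suite

The suite runs at desk scale by design: exhaustive decomposition checks
cover all tree shapes to 7 leaves plus 100 random 8–10 leaf trees;
partial-order oracles run on 200 random constraint sets of ≤ 200 residues;
projection conservation runs 50 seeded instances of 4–6 species × 120–200
bp; separation soundness runs ten 5-species × 2 kb instances; the
progressive-alignment reduction runs twenty 6–10 leaf instances; simulator
calibration uses a 50 kb branch. These sizes make the properties sharp
(exhaustive where an oracle is exhaustive, multi-seed where randomized)
while keeping the default run inexpensive.

## Limitations

- Rearrangements, inversions and translocations are out of scope; regions
  must be colinear (unscramble upstream).
- The independence guarantee holds only when the constraints are a subset
  of the true alignment and is void across truncated block boundaries.
- The built-in aligner is a deterministic baseline, not a competitive
  aligner; real use plugs in an external backend.
- Cluster batch systems are not integrated; parallelism is local forked
  workers.
- DNA alphabet only (`A,C,G,T,N`); no protein support.
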