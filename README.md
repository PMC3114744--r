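# metalign

Meta-alignment: scaling multiple sequence alignment (MSA) to long and deep
problems by partitioning them into smaller sub-problems, solving those with
an existing aligner, and reassembling the results into an alignment of the
full problem.

Modern statistically-motivated global aligners often cannot be run directly
on problems that are long (megabases per species) or deep (hundreds to
thousands of species) because their time and memory grow too fast. This
package implements two orthogonal, aligner-agnostic partitioning
strategies for such problems, aimed at comparative genomicists who want to
apply a favourite aligner beyond its native scale:

- **Length-wise partitioning** (`crumble_align`). Given sparse pairwise
  position constraints — aligned base pairs that induce a partial order ≺
  over all residues — the problem is tiled into *blocks*. A *separation*
  at an anchor position x assigns each species the interval between the
  first position not strictly below x and the least position aᵢ with
  x ≼ aᵢ; no residue left of a separation can be aligned past its right
  edge without contradicting the constraints. The region between two
  consecutive separations is a *core*; cores are mutually unalignable and
  hence independently alignable. Each block (core plus flanking
  separations) is aligned in parallel, shared separations are trimmed off
  both neighbours and realigned, and everything is concatenated. If the
  constraints are a subset of the true alignment, no truly homologous pair
  of residues is split across two cores.

- **Depth-wise partitioning** (`prune_align`). A rooted binary phylogeny
  is decomposed into sub-trees overlapping at cut nodes, minimising the
  number of sequential *stages* S subject to at most M sequences per
  sub-tree problem (leaves plus inferred roots), by a dynamic program that
  is linear in the number of species for fixed M. Sub-trees are aligned
  leaf-to-root — same-stage problems in parallel — a root sequence is
  inferred for each (majority-consensus "maximal" inference by default, or
  the nearest leaf sequence), parents align inferred roots as ordinary
  sequences, and the sub-alignments are finally merged along the inferred
  root guides. With M = 2, leaf-sequence inference, and no out-groups the
  procedure reduces exactly to progressive alignment.

The two compose: `meta_align` runs the tree decomposition with block
partitioning inside every sub-tree job, the configuration that scales to
very long *and* very deep problems. A hierarchical job executor
(`run_jobs`) with children/follow-on semantics runs the dynamic job trees
serially or on forked local workers with bit-identical results.

Also included: a deterministic built-in progressive aligner
(`progressive_align`, optimal affine-gap pairwise DP under the hood), a
wrapper for external command-line aligners (`external_backend`), an anchor
based constraint generator (`generate_anchor_constraints`), the *average
agreement* score between predicted and true alignments (`agreement`), and
a neutral-evolution simulator (HKY substitutions plus indels) that emits
leaf FASTA, the true alignment, and the tree (`random_tree`, `evolve`) so
every algorithm can be exercised without external binaries.

## Worked example

Simulate nine species over a tree of total length 1.13 substitutions/site,
sample 30% of the true residue pairs as constraints, and align by blocks:

```r
library(metalign)
tree  <- random_tree(9, total_length = 1.13, seed = 42)
truth <- evolve(tree, sim_config(root_length = 2000, seed = 43))
cs    <- constraints_from_truth(truth, fraction = 0.3, seed = 44)
cs
#> constraint_set: 9 sequences (17953 residues), 21116 constraints
tile_blocks(cs, core_size = 300)
#> block_tiling: 7 blocks over 9 sequences (core 300, max Inf)

aln <- crumble_align(truth$seqs, cs, core_size = 300,
                     mode = "parallel", workers = 4)
agreement(aln, truth$truth)
#> 0.8367
agreement(builtin_backend()(truth$seqs), truth$truth)   # direct run
#> 0.7692
```

The blockwise run scores at least as well as the direct run here — on
divergent problems the partitioning can *gain* accuracy, because each
sub-problem is easier — while each ~450-column block alignment can run in
parallel. The agreement score is the fraction of the predicted alignment's
pairwise residue/gap placements that also occur in the true alignment,
averaged over species pairs: identical alignments score 1, completely
disagreeing ones 0.

Depth-wise, capping sub-tree problems at four sequences needs only three
sequential stages for these nine species:

```r
min_stage_decomposition(tree, 4)
#> decomposition: 3 sub-trees, 3 stages (M = 4)
pr <- prune_align(truth$seqs, tree, M = 4, inference = "maximal",
                  use_outgroups = TRUE)
agreement(pr, truth$truth)
#> 0.8914
```

A command-line front-end for all of this (subcommands `simulate`,
`constraints`, `crumble`, `prune`, `align`, `score`) ships at
`inst/cli/metalign.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/metalign.R", package="metalign"))')" \
    crumble --fasta in.fa --constraints c.tsv --core-size 300 \
    --backend builtin --jobs 4 --out out.fa --maf out.maf
```

External aligners plug in with `--backend 'cmd:mafft {in} > {out}'`-style
templates; every backend result is checked against the projection
contract (each output row, gaps removed, must equal its input sequence).

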