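test_that("stage-minimizing decomposition matches exhaustive enumeration on small trees", {
  # all shapes up to 7 leaves, every feasible cap
  for (n in 2:7) {
    for (tree in all_tree_shapes(n)) {
      for (M in 2:n) {
        dec <- min_stage_decomposition(tree, M)
        expect_identical(dec$stage_count, oracle_min_stages(tree, M),
                         info = sprintf("n=%d M=%d", n, M))
      }
    }
  }
})

test_that("decomposition stage counts are optimal on random larger trees and non-increasing in M", {
  set.seed(505)
  for (rep in 1:12) {
    n <- sample(8:10, 1L)
    tree <- random_tree(n, 1.0, seed = 7000L + rep)
    prev <- Inf
    for (M in 2:n) {
      dec <- min_stage_decomposition(tree, M)
      expect_identical(dec$stage_count, oracle_min_stages(tree, M))
      expect_lte(dec$stage_count, prev)
      prev <- dec$stage_count
    }
  }
})

test_that("decomposition structure: leaves partitioned, cut nodes paired, stages ordered", {
  tree <- random_tree(12, 1.0, seed = 77)
  dec <- min_stage_decomposition(tree, 4L)
  leaves <- unlist(lapply(dec$problems, function(p) {
    vapply(Filter(function(m) m$type == "leaf", p$members), `[[`, 0L, "id")
  }))
  subroots <- unlist(lapply(dec$problems, function(p) {
    vapply(Filter(function(m) m$type == "subroot", p$members), `[[`, 0L, "id")
  }))
  roots <- vapply(dec$problems, `[[`, 0L, "root")
  ntip <- length(tree$tip.label)
  # frontier cap respected; every problem root except the tree root appears
  # as a frontier member exactly once; every leaf in exactly one problem
  expect_true(all(vapply(dec$problems, function(p) length(p$members), 0L) <= 4L))
  expect_setequal(subroots, setdiff(roots, ntip + 1L))
  expect_identical(anyDuplicated(subroots), 0L)
  expect_setequal(leaves, seq_len(ntip))
  expect_identical(anyDuplicated(leaves), 0L)
  for (p in dec$problems) {
    for (m in p$members) {
      if (m$type == "subroot") {
        child <- dec$problems[[which(roots == m$id)]]
        expect_lt(child$stage, p$stage)
      }
    }
  }
})

test_that("decomposition boundary cases and input validation", {
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  dec <- min_stage_decomposition(cherry, 2L)
  expect_identical(dec$stage_count, 2L)
  expect_length(dec$problems, 1L)

  quad <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_identical(min_stage_decomposition(quad, 4L)$stage_count, 2L)
  expect_length(min_stage_decomposition(quad, 4L)$problems, 1L)

  bal8 <- all_tree_shapes(8)[[which(vapply(all_tree_shapes(8), function(t) {
    max(ape::node.depth.edgelength(t)) == 3
  }, TRUE))[1L]]]
  dec8 <- min_stage_decomposition(bal8, 2L)
  expect_length(dec8$problems, 7L)           # one problem per internal node
  expect_identical(dec8$stage_count, 4L)     # leaf stage + one per level

  expect_error(min_stage_decomposition(cherry, 1L), "M must be >= 2")
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(min_stage_decomposition(poly, 2L), "binary")
})

test_that("majority-consensus inference follows counts, tie-break, and length", {
  expect_identical(infer_root_maximal(msa(c(x = "A", y = "A", z = "G"))), "A")
  expect_identical(infer_root_maximal(msa(c(x = "A", y = "C", z = "G"))), "A")
  expect_identical(infer_root_maximal(msa(c(x = "T", y = "G", z = "G"))), "G")
  set.seed(12)
  aln <- msa(setNames(c(random_dna(10), random_dna(10), random_dna(10)),
                      c("a", "b", "c")))
  expect_identical(nchar(infer_root_maximal(aln)), 10L)
  # gap cells never win a column
  gappy <- msa(c(x = "A-G", y = "ACG", z = "-C-"))
  expect_identical(infer_root_maximal(gappy), "ACG")
})

test_that("out-group selection minimizes path length with name tie-break", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:5):1);")
  sub <- ape::getMRCA(tree, c("A", "B"))
  expect_identical(select_outgroup(tree, sub), "C")
  expect_null(select_outgroup(tree, length(tree$tip.label) + 1L))
  tie <- ape::read.tree(text = "((A:1,B:1):1,(D:2,C:2):1);")
  expect_identical(select_outgroup(tie, ape::getMRCA(tie, c("A", "B"))), "C")
})

test_that("guide-based merging matches the naive expansion oracle", {
  # bijective (consensus-style) guides: column-wise splice, same column count
  parent <- msa(c(g1 = "ACGT", g2 = "TGCA"))
  g <- list(
    g1 = list(child = msa(c(p = "AC-GT", q = "ACT-T")), map = c(1L, 2L, 4L, 5L)),
    g2 = list(child = msa(c(r = "TGCA")), map = 1:4))
  out <- merge_alignments(parent, g)
  expect_identical(msa_chars(out), msa_chars(oracle_merge(parent, g)))
  expect_setequal(names(out), c("p", "q", "r"))

  # consensus-style guides hit every child column: a pure column splice
  bij <- list(
    g1 = list(child = msa(c(p = "AC-GT", q = "ACT-T")), map = 1:5),
    g2 = list(child = msa(c(r = "TGCAG")), map = 1:5))
  parent_b <- msa(c(g1 = "ACGTT", g2 = "TGCAG"))
  out_b <- merge_alignments(parent_b, bij)
  expect_identical(msa_ncol(out_b), msa_ncol(parent_b))
  expect_identical(msa_chars(out_b), msa_chars(oracle_merge(parent_b, bij)))

  # single-leaf child: merge relabels the row
  parent2 <- msa(c(gL = "AC-T", x = "ACGT"))
  g2 <- list(gL = list(child = msa(c(leaf = "ACT"), check = FALSE), map = 1:3))
  out2 <- merge_alignments(parent2, g2)
  expect_identical(msa_chars(out2), msa_chars(msa(c(leaf = "AC-T", x = "ACGT"))))

  # gapped guides with unmapped child columns (leaf-sequence guides)
  parent3 <- msa(c(gA = "AA--CC", gB = "-TTG-A", z = "GGGGGG"))
  g3 <- list(
    gA = list(child = msa(c(u = "A-AC-C", v = "GTA-TC")), map = c(1L, 3L, 4L, 6L)),
    gB = list(child = msa(c(w = "TT-G-A", s = "T-CGAA")), map = c(1L, 2L, 4L, 6L)))
  out3 <- merge_alignments(parent3, g3)
  expect_identical(msa_chars(out3), msa_chars(oracle_merge(parent3, g3)))
  expect_identical(msa_project(out3)[["u"]], "AACC")
  expect_identical(msa_project(out3)[["w"]], "TTGA")

  bad <- list(gA = list(child = msa(c(u = "ACGT")), map = c(3L, 1L, 2L, 4L)))
  expect_error(merge_alignments(msa(c(gA = "ACGT")), bad), "not strictly increasing")
})

test_that("prune with a large cap reduces to the direct backend alignment", {
  ts <- sim_instance(6, 150, 0.4, seed = 201)
  backend <- builtin_backend()
  direct <- backend(ts$seqs, ts$tree)
  out <- prune_align(ts$seqs, ts$tree, M = 99L, backend = backend)
  expect_identical(unclass(out), unclass(msa(unclass(direct)[names(ts$seqs)])))
})

test_that("prune at cap two with leaf-sequence inference equals progressive alignment", {
  for (rep in 1:4) {
    ts <- sim_instance(sample(5:8, 1L), 120, 0.5, seed = 300L + rep)
    p <- prune_align(ts$seqs, ts$tree, M = 2L, inference = "nearest_leaf",
                     use_outgroups = FALSE, mode = "serial")
    q <- progressive_align(ts$seqs, ts$tree)
    expect_identical(unclass(p), unclass(q), info = paste("rep", rep))
  }
})

test_that("prune conserves projections across caps, inference methods, out-groups", {
  ts <- sim_instance(9, 200, 0.6, seed = 401)
  for (M in c(2L, 3L, 5L)) {
    for (inf in c("maximal", "nearest_leaf")) {
      for (og in c(FALSE, TRUE)) {
        out <- prune_align(ts$seqs, ts$tree, M = M, inference = inf,
                           use_outgroups = og)
        expect_true(projections_match(out, ts$seqs),
                    info = sprintf("M=%d %s og=%s", M, inf, og))
        expect_setequal(names(out), names(ts$seqs))
      }
    }
  }
})

test_that("moderate caps recover alignments close to the full-problem run", {
  ts <- sim_instance(12, 300, 0.5, seed = 501)
  full <- prune_align(ts$seqs, ts$tree, M = 99L)
  a_full <- agreement(full, ts$truth)
  part <- prune_align(ts$seqs, ts$tree, M = 5L, inference = "maximal",
                      use_outgroups = TRUE)
  a_part <- agreement(part, ts$truth)
  expect_gte(a_part, a_full - 0.05)
})

test_that("prune validates inputs", {
  ts <- sim_instance(4, 60, 0.3, seed = 601)
  expect_error(prune_align(ts$seqs[-1L], ts$tree, M = 3L), "missing sequence")
  expect_error(prune_align(ts$seqs, ts$tree, M = 1L), "M must be")
})
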