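# shared fixture: a fully aligned column induces the narrowest separation
aligned_column_cs <- function(seqs, col) {
  nms <- names(seqs)
  constraint_set(seqs, data.frame(
    seq_a = nms[1L], pos_a = col, seq_b = nms[-1L], pos_b = col))
}

test_that("a fully aligned column yields a width-1 separation in every species", {
  seqs <- setNames(rep(random_dna(30, seed = 1), 4), paste0("s", 1:4))
  cs <- aligned_column_cs(seqs, 12L)
  sep <- find_separation(cs, list("s1", 12L))
  expect_identical(unname(sep$start), rep(12L, 4))
  expect_identical(unname(sep$end), rep(13L, 4))
})

test_that("an empty constraint set leaves unanchored species unbounded", {
  seqs <- c(a = random_dna(20, seed = 2), b = random_dna(25), c = random_dna(30))
  cs <- constraint_set(seqs)
  sep <- find_separation(cs, list("a", 7L))
  expect_identical(sep$start[["a"]], 7L)
  expect_identical(sep$end[["a"]], 8L)
  # no bounding constraint: the separation extends to the sequence end
  expect_identical(sep$start[["b"]], 0L)
  expect_identical(sep$end[["b"]], 25L)
  expect_identical(sep$start[["c"]], 0L)
  expect_identical(sep$end[["c"]], 30L)
})

test_that("separations match the exhaustive poset oracle on staircase and random sets", {
  stair <- constraint_set(
    c(A = "ACGTACGTAC", B = "GTACGTACGT", C = "TTTTACGTCC"),
    data.frame(seq_a = c("A", "B", "A"), pos_a = c(2L, 5L, 7L),
               seq_b = c("B", "C", "C"), pos_b = c(1L, 4L, 8L)))
  r <- oracle_reach_matrix(stair)
  for (pos in c(0L, 2L, 5L, 9L)) {
    sep <- find_separation(stair, list("A", pos))
    osep <- oracle_separation(r, stair, list("A", pos))
    expect_identical(sep$start, osep$start, info = paste("start at", pos))
    expect_identical(sep$end, osep$end, info = paste("end at", pos))
  }
  for (rep in 1:20) {
    cs <- random_truth_cs(nseq = 3L, ncol = 15L, gap_prob = 0.2,
                          fraction = 0.5, seed = 2200L + rep)
    r <- oracle_reach_matrix(cs)
    set.seed(rep)
    s <- sample(names(cs$seqs), 1L)
    anchor <- list(s, sample(cs$lens[[s]], 1L) - 1L)
    sep <- find_separation(cs, anchor)
    osep <- oracle_separation(r, cs, anchor)
    expect_identical(sep$start, osep$start)
    expect_identical(sep$end, osep$end)
  }
})

test_that("find_separation rejects inconsistent constraint sets", {
  seqs <- c(A = "ACGT", B = "ACGT")
  bad <- constraint_set(seqs, data.frame(seq_a = "A", pos_a = c(0L, 1L),
                                         seq_b = "B", pos_b = c(1L, 0L)))
  expect_error(find_separation(bad, list("A", 0L)), "inconsistent")
})

validate_tiling <- function(tl) {
  nms <- tl$species
  K <- length(tl$blocks)
  for (s in nms) {
    covered <- integer(0)
    for (k in seq_len(K)) {
      b <- tl$blocks[[k]]
      expect_lte(b$start[[s]], b$core_start[[s]])
      expect_lte(b$core_start[[s]], b$core_end[[s]])
      expect_lte(b$core_end[[s]], b$end[[s]])
      if (is.finite(tl$max_block_size) && k < K) {
        expect_lte(b$end[[s]] - b$start[[s]], tl$max_block_size)
      }
      if (k < K) {  # right separation shared with the next block
        expect_identical(b$core_end[[s]], tl$seps[[k]]$start[[s]])
        expect_identical(b$end[[s]], tl$seps[[k]]$end[[s]])
        expect_identical(tl$blocks[[k + 1L]]$start[[s]], tl$seps[[k]]$start[[s]])
        expect_identical(tl$blocks[[k + 1L]]$core_start[[s]], tl$seps[[k]]$end[[s]])
      }
      covered <- c(covered, seq2(b$start[[s]], b$end[[s]]))
    }
    # cores partition what separations do not claim; full coverage, in order
    expect_identical(sort(unique(covered)), seq2(0L, tl$lens[[s]]))
    cores <- unlist(lapply(tl$blocks, function(b) seq2(b$core_start[[s]], b$core_end[[s]])))
    expect_identical(anyDuplicated(cores), 0L)
  }
}

seq2 <- function(from, to) if (to > from) seq.int(from, to - 1L) else integer(0)

test_that("tiling with a huge core gives a single all-spanning block", {
  seqs <- c(x = random_dna(40, seed = 3), y = random_dna(44))
  cs <- generate_anchor_constraints(seqs, k = 6)
  tl <- tile_blocks(cs, core_size = 1000L)
  expect_length(tl$blocks, 1L)
  expect_identical(unname(tl$blocks[[1L]]$end), unname(as.integer(cs$lens)))
  validate_tiling(tl)
})

test_that("fully constrained identical sequences tile into width-1 separations", {
  L <- 80L
  s <- random_dna(L, seed = 4)
  seqs <- setNames(rep(s, 3), c("a", "b", "c"))
  df <- do.call(rbind, lapply(c("b", "c"), function(o) {
    data.frame(seq_a = "a", pos_a = 0:(L - 1L), seq_b = o, pos_b = 0:(L - 1L))
  }))
  cs <- constraint_set(seqs, df)
  tl <- tile_blocks(cs, core_size = L %/% 4L)
  expect_length(tl$blocks, 4L)
  for (sep in tl$seps) {
    expect_identical(unname(sep$end - sep$start), rep(1L, 3))
  }
  validate_tiling(tl)
})

test_that("an empty constraint set forces max-size truncation blocks", {
  B <- 25L
  seqs <- setNames(rep(random_dna(100, seed = 5), 3), c("r", "s", "t"))
  cs <- constraint_set(seqs)
  tl <- tile_blocks(cs, core_size = B, max_block_size = B)
  validate_tiling(tl)
  widths <- vapply(head(tl$blocks, -1L), function(b) {
    unname(b$end - b$start)
  }, integer(3))
  expect_true(all(widths == B))
})

test_that("decreasing core size never decreases the block count", {
  ts <- sim_instance(4, 400, 0.3, seed = 31)
  cs <- constraints_from_truth(ts, 0.4, seed = 8)
  counts <- vapply(c(200L, 100L, 50L, 25L), function(core) {
    length(tile_blocks(cs, core)$blocks)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  validate_tiling(tile_blocks(cs, 50L))
})

test_that("tiling validates its inputs", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT")
  cs <- constraint_set(seqs)
  expect_error(tile_blocks(cs, 0L), "core_size")
  expect_error(tile_blocks(cs, 10L, max_block_size = 5L), "max_block_size")
})

test_that("trimming removes exactly the separation residues", {
  aln <- msa(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT", c = "ACGTACGTACGT"))
  sep0 <- structure(list(start = c(a = 0L, b = 0L, c = 0L),
                         end = c(a = 0L, b = 0L, c = 0L)), class = "separation")
  tr <- trim_block_alignment(aln, "right", sep0)
  expect_identical(unclass(tr$kept), unclass(aln))
  expect_length(tr$removed, 0L)

  sep3 <- structure(list(start = c(a = 9L, b = 9L, c = 9L),
                         end = c(a = 12L, b = 12L, c = 12L)), class = "separation")
  tr <- trim_block_alignment(aln, "right", sep3)
  expect_identical(msa_ncol(tr$kept), 9L)
  expect_identical(unname(tr$removed), rep("CGT", 3))
  expect_identical(unname(msa_project(tr$kept)), rep("ACGTACGTA", 3))
})

test_that("trimming a gapped alignment equals the naive masking oracle", {
  aln <- msa(c(x = "AC-GTA--CG", y = "-CTG--AT-G", z = "ACTG-AATCG"))
  sep <- structure(list(start = c(x = 0L, y = 0L, z = 0L),
                        end = c(x = 2L, y = 1L, z = 3L)), class = "separation")
  tr <- trim_block_alignment(aln, "left", sep)
  # oracle: gap the first w residues of each row, drop empty columns
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  for (s in names(aln)) {
    w <- (sep$end - sep$start)[[s]]
    if (w > 0) m[s, which(m[s, ] != "-")[seq_len(w)]] <- "-"
  }
  m <- m[, colSums(m != "-") > 0, drop = FALSE]
  expect_identical(unname(unclass(tr$kept)),
                   unname(apply(m, 1L, paste0, collapse = "")))
  expect_identical(unname(tr$removed), c("AC", "C", "ACT"))
})

test_that("a single-block problem reduces to the direct backend alignment", {
  ts <- sim_instance(4, 150, 0.4, seed = 61)
  cs <- constraints_from_truth(ts, 0.5, seed = 6)
  backend <- builtin_backend()
  direct <- backend(ts$seqs)
  out <- crumble_align(ts$seqs, cs, backend, core_size = 10000L)
  expect_identical(unclass(out), unclass(msa(unclass(direct)[names(ts$seqs)])))
})

test_that("identical fully constrained sequences crumble to a gapless perfect alignment", {
  L <- 300L
  s <- random_dna(L, seed = 71)
  seqs <- setNames(rep(s, 9), paste0("sp", 1:9))
  truth <- msa(seqs)
  ts <- list(seqs = seqs, truth = truth)
  cs <- constraints_from_truth(ts, 1.0, seed = 1)
  out <- crumble_align(seqs, cs, core_size = 50L)
  expect_false(any(grepl("-", unclass(out), fixed = TRUE)))
  expect_identical(agreement(out, truth), 1)
})

test_that("crumble conserves projections and reports failing blocks", {
  ts <- sim_instance(5, 350, 0.5, seed = 81)
  cs <- constraints_from_truth(ts, 0.3, seed = 2)
  out <- crumble_align(ts$seqs, cs, core_size = 60L)
  expect_true(projections_match(out, ts$seqs))

  failing <- function(seqs, guide_tree = NULL) stop("boom")
  expect_error(crumble_align(ts$seqs, cs, failing, core_size = 60L),
               "backend failed on block")
})

test_that("no aligned pair in the crumble output crosses a separation boundary", {
  # the partial-order guarantee: residues left of a separation may not be
  # aligned with residues right of it
  ts <- sim_instance(4, 300, 0.4, seed = 91)
  cs <- constraints_from_truth(ts, 0.4, seed = 3)
  tl <- tile_blocks(cs, 60L)
  out <- crumble_align(ts$seqs, cs, core_size = 60L)
  nms <- names(ts$seqs)
  for (p in combn(nms, 2L, simplify = FALSE)) {
    ev <- project_pair(out, p[1L], p[2L])
    ev <- ev[!is.na(ev$x) & !is.na(ev$y), , drop = FALSE]
    for (sep in tl$seps) {
      bad <- (ev$x < sep$start[[p[1L]]] & ev$y >= sep$end[[p[2L]]]) |
        (ev$y < sep$start[[p[2L]]] & ev$x >= sep$end[[p[1L]]])
      expect_false(any(bad))
    }
  }
})
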