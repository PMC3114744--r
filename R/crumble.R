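#' Find a separation through a sparse alignment
#'
#' Given an anchor base position x, a separation assigns to each sequence a
#' half-open interval such that every residue strictly left of the interval
#' strictly precedes x under the constraint partial order, and every residue
#' at-or-right of the interval's end strictly follows x. Nothing left of a
#' separation can therefore be aligned past its right edge without
#' contradicting the constraints. Per sequence the interval runs from the
#' projection of x's equivalence class (or the first position not strictly
#' below x) to the least position a_i with x preceding-or-equal a_i,
#' inclusive; sequences with no such bounding position have their interval
#' extended to the sequence end.
#'
#' @param cs A consistent [constraint_set].
#' @param anchor Position `list(name, index)` (0-based).
#' @return A `separation`: list with named integer vectors `start` and
#'   `end` (0-based, half-open) and the `anchor`.
#' @export
find_separation <- function(cs, anchor) {
  chk <- check_consistency(cs)
  if (!chk$consistent) stop_input("constraint set is inconsistent")
  .find_separation(cs, anchor)
}

.find_separation <- function(cs, anchor) {
  anchor <- as_position(cs, anchor)
  lens <- cs$lens
  u <- closure_thresholds(cs, anchor$name, anchor$pos, up = TRUE)
  d <- closure_thresholds(cs, anchor$name, anchor$pos, up = FALSE)
  cls_x <- class_index(cs$index, anchor$name, anchor$pos)
  nms <- names(lens)
  start <- end <- setNames(integer(length(nms)), nms)
  for (s in nms) {
    # end: one past the least position at-or-after x; sequence end if none
    end[s] <- if (is.na(u[[s]])) lens[[s]] else u[[s]] + 1L
    # start: first position not strictly below x
    D <- d[[s]]
    if (is.na(D)) {
      start[s] <- 0L
    } else {
      equal_x <- (s == anchor$name && D == anchor$pos) ||
        (!is.na(cls_x) && identical(class_index(cs$index, s, D), cls_x))
      start[s] <- if (equal_x) D else D + 1L
    }
    if (start[s] > end[s]) start[s] <- end[s]
  }
  structure(list(start = start, end = end, anchor = anchor), class = "separation")
}

#' @export
print.separation <- function(x, ...) {
  cat(sprintf("separation at %s:%d\n", x$anchor$name, x$anchor$pos))
  for (s in names(x$start)) {
    cat(sprintf("  %-12s [%d, %d)\n", s, x$start[[s]], x$end[[s]]))
  }
  invisible(x)
}

#' Tile a constrained alignment problem into blocks
#'
#' Greedy left-to-right scan: advance approximately `core_size` residues in
#' the first (reference) sequence past the previous separation end, find a
#' separation there, and emit a block (left separation + core + right
#' separation). A block exceeding `max_block_size` residues in a sequence is
#' truncated there; the truncated-off sequence becomes part of the next
#' block and that boundary carries no separation (the independence guarantee
#' is void across truncated boundaries). The last block absorbs all
#' remainders.
#'
#' @param cs A consistent [constraint_set].
#' @param core_size Target core size in reference-sequence residues (> 0).
#' @param max_block_size Maximum block width per sequence
#'   (>= `core_size`; default unlimited).
#' @return A `block_tiling`: list with `species`, `blocks` (each with
#'   per-species `start`/`end` and `core_start`/`core_end`), `seps`
#'   (the K-1 shared separations), and the parameters.
#' @export
tile_blocks <- function(cs, core_size, max_block_size = Inf) {
  core_size <- as.integer(core_size)
  if (is.na(core_size) || core_size <= 0L) stop_input("core_size must be > 0")
  if (max_block_size < core_size) stop_input("max_block_size must be >= core_size")
  chk <- check_consistency(cs)
  if (!chk$consistent) stop_input("constraint set is inconsistent")
  nms <- names(cs$seqs)
  lens <- setNames(as.integer(cs$lens), nms)
  ref <- nms[1L]
  done <- setNames(integer(length(nms)), nms)
  blk_start <- done  # left edge of the block being formed
  blocks <- list()
  seps <- list()
  repeat {
    anchor_pos <- done[[ref]] + core_size - 1L
    # a separation at (or past) the reference's last residue adds nothing:
    # the final block absorbs the remainder
    if (anchor_pos >= lens[[ref]] - 1L) {
      blocks[[length(blocks) + 1L]] <- list(
        index = length(blocks) + 1L,
        start = blk_start, end = lens,
        core_start = done, core_end = lens)
      break
    }
    sep <- .find_separation(cs, list(ref, anchor_pos))
    s <- pmax(sep$start, done)
    e <- pmax(sep$end, s)
    if (is.finite(max_block_size)) {
      over <- which(e - blk_start > max_block_size)
      for (i in over) {
        cut <- blk_start[[i]] + as.integer(max_block_size)
        # cut never lands left of the finished region: the previous
        # separation is no wider than a full block
        s[i] <- cut
        e[i] <- cut
      }
    }
    blocks[[length(blocks) + 1L]] <- list(
      index = length(blocks) + 1L,
      start = blk_start, end = e,
      core_start = done, core_end = s)
    seps[[length(seps) + 1L]] <- structure(
      list(start = s, end = e, anchor = sep$anchor), class = "separation")
    blk_start <- s
    done <- e
    if (length(blocks) > sum(lens) + 1L) {
      stop_internal("tiling failed to make progress")
    }
  }
  structure(list(species = nms, lens = lens, core_size = core_size,
                 max_block_size = max_block_size,
                 blocks = blocks, seps = seps),
            class = "block_tiling")
}

#' @export
print.block_tiling <- function(x, ...) {
  cat(sprintf("block_tiling: %d blocks over %d sequences (core %d, max %s)\n",
              length(x$blocks), length(x$species), x$core_size,
              format(x$max_block_size)))
  invisible(x)
}

#' Trim a separation off one flank of a block alignment
#'
#' Every cell whose residue belongs to the separation is replaced by a gap
#' and all-gap columns are removed. The separation residues must form a
#' contiguous prefix (`side = "left"`) or suffix (`side = "right"`) of each
#' sequence's residues in the alignment; trimming is by residue count, so
#' the removed residues are exactly the separation interval.
#'
#' @param aln Block alignment ([msa]).
#' @param side `"left"` or `"right"`.
#' @param sep A `separation` (absolute per-species intervals); species
#'   absent from `aln` are ignored.
#' @return List with `kept` (trimmed [msa]) and `removed` (named character
#'   vector of removed residues per species, in sequence order).
#' @export
trim_block_alignment <- function(aln, side = c("left", "right"), sep) {
  side <- match.arg(side)
  widths <- sep$end - sep$start
  widths <- widths[names(widths) %in% names(aln)]
  widths <- widths[widths > 0L]
  if (length(widths) == 0L) {
    return(list(kept = aln, removed = setNames(character(0), character(0))))
  }
  m <- msa_matrix(aln)
  removed <- setNames(character(length(widths)), names(widths))
  for (s in names(widths)) {
    cells <- which(m[s, ] != GAP)
    w <- widths[[s]]
    if (w > length(cells)) {
      stop_internal("separation wider than row '", s, "' in block alignment")
    }
    drop <- if (side == "left") head(cells, w) else tail(cells, w)
    removed[s] <- collapse(m[s, drop])
    m[s, drop] <- GAP
  }
  keep_cols <- colSums(m != GAP) > 0L
  m <- m[, keep_cols, drop = FALSE]
  list(kept = msa_from_matrix(m, drop_allgap = FALSE, check = FALSE),
       removed = removed)
}

#' Align a long problem by block partitioning
#'
#' The pipeline: tile the constraints into blocks; align every block in
#' parallel with the backend; trim each shared separation off both adjacent
#' block alignments; realign each separation's pooled residues (in
#' parallel); concatenate kept cores and separation alignments in order.
#' Every output row projects to its input sequence.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param cs A consistent [constraint_set] over exactly these sequences.
#' @param backend A backend function (see [builtin_backend],
#'   [external_backend], [resolve_backend]).
#' @param core_size,max_block_size Tiling parameters (see [tile_blocks]).
#' @param mode,workers Executor mode and worker count (see [run_jobs]).
#' @return An [msa] with rows in input order.
#' @export
crumble_align <- function(seqs, cs, backend = builtin_backend(),
                          core_size, max_block_size = Inf,
                          mode = c("serial", "parallel"), workers = 1L) {
  mode <- match.arg(mode)
  backend <- resolve_backend(backend)
  if (length(seqs) == 0L) return(msa(character(0)))
  if (!identical(unname(cs$seqs[names(seqs)]), unname(seqs))) {
    stop_input("constraint set does not cover exactly the input sequences")
  }
  tiling <- tile_blocks(cs, core_size, max_block_size)
  root <- job("crumble", crumble_root_action,
              args = list(seqs = seqs, tiling = tiling, backend = backend))
  run_jobs(root, mode = mode, workers = workers)$value
}

crumble_root_action <- function(seqs, tiling, backend) {
  block_jobs <- lapply(tiling$blocks, function(b) {
    sub <- substr(seqs, b$start[names(seqs)] + 1L, b$end[names(seqs)])
    sub <- sub[nchar(sub) > 0L]
    job(paste0("block_", b$index), function(sub, idx) {
      t0 <- proc.time()[["elapsed"]]
      aln <- tryCatch(backend(sub),
                      error = function(e) stop_backend(
                        "backend failed on block ", idx, ": ", conditionMessage(e)))
      log_at("info", sprintf("block %d: %d seqs, %d residues, %.2fs",
                             idx, length(sub), sum(nchar(sub)),
                             proc.time()[["elapsed"]] - t0))
      aln
    }, args = list(sub = sub, idx = b$index))
  })
  job_result(value = NULL, children = block_jobs,
             follow_on = function(value, block_alns) {
               crumble_trim_phase(seqs, tiling, backend, unname(block_alns))
             })
}

crumble_trim_phase <- function(seqs, tiling, backend, block_alns) {
  K <- length(tiling$blocks)
  kept <- block_alns
  for (k in seq_along(tiling$seps)) {
    kept[[k]] <- trim_block_alignment(kept[[k]], "right", tiling$seps[[k]])$kept
    kept[[k + 1L]] <- trim_block_alignment(kept[[k + 1L]], "left", tiling$seps[[k]])$kept
  }
  sep_jobs <- lapply(seq_along(tiling$seps), function(k) {
    sp <- tiling$seps[[k]]
    sub <- substr(seqs, sp$start[names(seqs)] + 1L, sp$end[names(seqs)])
    sub <- sub[nchar(sub) > 0L]
    job(paste0("sep_", k), function(sub, idx) {
      aln <- tryCatch(backend(sub),
                      error = function(e) stop_backend(
                        "backend failed on separation ", idx, ": ", conditionMessage(e)))
      log_at("info", sprintf("separation %d realigned: %d seqs, %d residues",
                             idx, length(sub), sum(nchar(sub))))
      aln
    }, args = list(sub = sub, idx = k))
  })
  job("crumble_assemble_phase", function() {
    job_result(value = NULL, children = sep_jobs,
               follow_on = function(value, sep_alns) {
                 job("crumble_concat", function() {
                   pieces <- vector("list", 2L * K - 1L)
                   pieces[seq(1L, 2L * K - 1L, by = 2L)] <- kept
                   if (K > 1L) pieces[seq(2L, 2L * K - 2L, by = 2L)] <- unname(sep_alns)
                   out <- msa_concat(pieces, names(seqs))
                   msa(unclass(out)[names(seqs)])
                 })
               })
  })
}
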