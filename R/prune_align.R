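node_label <- function(id) paste0("node", id)

#' Align a deep problem by phylogeny decomposition
#'
#' Decomposes the tree into minimum-stage sub-trees ([min_stage_decomposition]),
#' aligns each sub-tree problem leaf-to-root — same-stage problems run as
#' independent child jobs under the executor — infers a root sequence for
#' every sub-tree (used as a member sequence in its parent's problem), and
#' finally merges all sub-alignments bottom-up along the inferred root
#' guides. Optionally each problem additionally includes the out-group leaf
#' closest to its root (dropped from the alignment afterwards).
#'
#' @param seqs Named character vector of DNA sequences; names must equal
#'   the tree's leaf labels.
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param M Maximum sequences per sub-tree problem (>= 2).
#' @param backend A backend function or selection string
#'   (see [resolve_backend]).
#' @param inference Root inference method: `"maximal"` (majority consensus
#'   per column, the longest root that fits the alignment) or
#'   `"nearest_leaf"` (the sub-tree's closest leaf sequence, by branch
#'   length, ties by name).
#' @param use_outgroups Include out-group context sequences.
#' @param mode,workers Executor mode and workers (see [run_jobs]).
#' @return An [msa] over the leaves, rows in input order.
#' @export
prune_align <- function(seqs, tree, M, backend = builtin_backend(),
                        inference = c("maximal", "nearest_leaf"),
                        use_outgroups = FALSE,
                        mode = c("serial", "parallel"), workers = 1L) {
  inference <- match.arg(inference)
  mode <- match.arg(mode)
  backend <- resolve_backend(backend)
  check_tree(tree)
  if (!setequal(tree$tip.label, names(seqs))) {
    miss <- setdiff(tree$tip.label, names(seqs))
    stop_input("missing sequence for leaf: ", collapse(miss))
  }
  if (any(grepl("^node[0-9]+$", names(seqs)))) {
    stop_input("leaf names of the form 'node<digits>' are reserved")
  }
  dec <- min_stage_decomposition(tree, M)
  dists <- if (use_outgroups || inference == "nearest_leaf") ape::dist.nodes(tree) else NULL
  state <- new.env(parent = emptyenv())
  state$results <- vector("list", length(dec$problems))
  root_job <- prune_stage_job(1L, dec, seqs, tree, backend, inference,
                              use_outgroups, dists, state)
  run_jobs(root_job, mode = mode, workers = workers)$value
}

# Chain of stage jobs: each stage's problems are independent children; the
# follow-on records their inferred roots and schedules the next stage, and
# after the last stage performs the bottom-up merge.
prune_stage_job <- function(stage_idx, dec, seqs, tree, backend, inference,
                            use_outgroups, dists, state) {
  stages <- sort(unique(vapply(dec$problems, `[[`, 0L, "stage")))
  s <- stages[stage_idx]
  pids <- which(vapply(dec$problems, `[[`, 0L, "stage") == s)
  job(paste0("stage_", s), function() {
    kids <- lapply(pids, function(pid) {
      inputs <- problem_inputs(pid, dec, seqs, tree, use_outgroups, dists, state)
      job(paste0("subtree_", dec$problems[[pid]]$root),
          solve_subtree_problem,
          args = list(inputs = inputs, backend = backend,
                      inference = inference, pid = pid))
    })
    job_result(value = NULL, children = kids, follow_on = function(value, childvals) {
      for (k in seq_along(pids)) state$results[[pids[k]]] <- childvals[[k]]
      if (stage_idx < length(stages)) {
        prune_stage_job(stage_idx + 1L, dec, seqs, tree, backend, inference,
                        use_outgroups, dists, state)
      } else {
        job("prune_merge", function() {
          out <- merge_decomposition(dec, state$results)
          msa(unclass(out)[names(seqs)])
        })
      }
    })
  })
}

# Assemble one sub-tree problem's concrete inputs from the current state.
problem_inputs <- function(pid, dec, seqs, tree, use_outgroups, dists, state) {
  p <- dec$problems[[pid]]
  member_rows <- vapply(p$members, function(m) {
    if (m$type == "leaf") tree$tip.label[m$id] else node_label(m$id)
  }, "")
  member_seqs <- setNames(vapply(seq_along(p$members), function(k) {
    m <- p$members[[k]]
    if (m$type == "leaf") {
      seqs[[tree$tip.label[m$id]]]
    } else {
      cpid <- which(vapply(dec$problems, `[[`, 0L, "root") == m$id)
      state$results[[cpid]]$inferred_seq
    }
  }, ""), member_rows)
  gt <- induced_guide_tree(tree, p, member_rows)
  og <- NULL
  if (use_outgroups) {
    og_name <- select_outgroup(tree, p$root, dists)
    if (!is.null(og_name) && !og_name %in% member_rows) {
      og <- setNames(seqs[og_name], og_name)
      d <- dists[match(og_name, tree$tip.label), p$root]
      gt <- attach_outgroup(gt, og_name, d)
    }
  }
  # nearest-leaf designated row: member minimizing branch distance from the
  # problem root to the member node plus, for inferred members, the depth of
  # their own representative; ties by underlying leaf name
  rep_row <- rep_leaf <- NA_character_
  rep_depth <- NA_real_
  if (!is.null(dists)) {
    cand <- lapply(seq_along(p$members), function(k) {
      m <- p$members[[k]]
      if (m$type == "leaf") {
        list(row = member_rows[k], leaf = tree$tip.label[m$id],
             depth = dists[m$id, p$root])
      } else {
        cpid <- which(vapply(dec$problems, `[[`, 0L, "root") == m$id)
        r <- state$results[[cpid]]
        list(row = member_rows[k], leaf = r$rep_leaf,
             depth = dists[m$id, p$root] + r$rep_depth)
      }
    })
    depths <- vapply(cand, `[[`, 0, "depth")
    leaves <- vapply(cand, `[[`, "", "leaf")
    best <- order(depths, leaves)[1L]
    rep_row <- cand[[best]]$row
    rep_leaf <- cand[[best]]$leaf
    rep_depth <- cand[[best]]$depth
  }
  list(member_seqs = member_seqs, guide_tree = gt, outgroup = og,
       rep_row = rep_row, rep_leaf = rep_leaf, rep_depth = rep_depth,
       root = p$root)
}

# Runs inside a (possibly forked) child job: pure function of its inputs.
solve_subtree_problem <- function(inputs, backend, inference, pid) {
  t0 <- proc.time()[["elapsed"]]
  all_seqs <- c(inputs$member_seqs, inputs$outgroup)
  aln <- tryCatch(backend(all_seqs, inputs$guide_tree),
                  error = function(e) stop_backend(
                    "backend failed on sub-tree at node ", inputs$root, ": ",
                    conditionMessage(e)))
  if (!is.null(inputs$outgroup)) {
    m <- msa_matrix(aln)
    m <- m[setdiff(rownames(m), names(inputs$outgroup)), , drop = FALSE]
    aln <- msa_from_matrix(m, drop_allgap = TRUE, check = FALSE)
  }
  aln <- msa(unclass(aln)[names(inputs$member_seqs)], check = FALSE)
  if (inference == "maximal") {
    inferred <- infer_root_maximal(aln)
    map <- seq_len(msa_ncol(aln))
  } else {
    inferred <- msa_project(aln, inputs$rep_row)[[1L]]
    map <- guide_map_from_row(aln, inputs$rep_row)
  }
  log_at("info", sprintf("sub-tree node %d: %d seqs, %d cols, %.2fs",
                         inputs$root, length(all_seqs), msa_ncol(aln),
                         proc.time()[["elapsed"]] - t0))
  list(aln = aln, inferred_seq = inferred, inferred_map = map,
       rep_leaf = inputs$rep_leaf, rep_depth = inputs$rep_depth)
}

# Induced guide tree over a problem's frontier: the decomposition sub-tree
# with each member contracted to a tip (inferred members keep the branch
# above their cut node).
induced_guide_tree <- function(tree, p, member_rows) {
  if (length(member_rows) == 1L) return(NULL)
  kids <- children_list(tree)
  blen <- branch_lengths_by_node(tree)
  boundary <- setNames(member_rows, vapply(p$members, `[[`, 0L, "id"))
  rec <- function(node) {
    key <- as.character(node)
    if (!is.null(boundary[key]) && !is.na(boundary[key])) {
      return(boundary[[key]])
    }
    ch <- kids[[node]]
    sprintf("(%s:%.10g,%s:%.10g)", rec(ch[1L]), blen[ch[1L]],
            rec(ch[2L]), blen[ch[2L]])
  }
  txt <- paste0(rec(p$root), ";")
  tr <- ape::read.tree(text = txt)
  check_tree(tr)
}

attach_outgroup <- function(gt, og_name, dist) {
  if (is.null(gt)) return(NULL)
  inner <- sub(";$", "", ape::write.tree(gt, digits = 10))
  ape::read.tree(text = sprintf("(%s:0,%s:%.10g);", inner, og_name, dist))
}

# Bottom-up merge: each problem's alignment absorbs its children's merged
# alignments along the inferred-root guide maps.
merge_decomposition <- function(dec, results) {
  by_root <- setNames(seq_along(dec$problems),
                      vapply(dec$problems, `[[`, 0L, "root"))
  merged_one <- function(pid) {
    p <- dec$problems[[pid]]
    r <- results[[pid]]
    subroots <- Filter(function(m) m$type == "subroot", p$members)
    if (length(subroots) == 0L) {
      return(list(aln = r$aln, colmap = seq_len(msa_ncol(r$aln))))
    }
    guides <- list()
    for (m in subroots) {
      cpid <- by_root[[as.character(m$id)]]
      child <- merged_one(cpid)
      cres <- results[[cpid]]
      guides[[node_label(m$id)]] <- list(
        child = child$aln,
        map = child$colmap[cres$inferred_map])
    }
    out <- merge_alignments(r$aln, guides)
    list(aln = out, colmap = attr(out, "parent_columns"))
  }
  merged_one(by_root[[as.character(length(dec$tree$tip.label) + 1L)]])$aln
}

#' Combined depth- and length-wise meta-alignment
#'
#' Runs the phylogeny decomposition with block partitioning applied inside
#' every sub-tree problem: each sub-problem generates anchor constraints
#' over its member sequences and is aligned with [crumble_align] around the
#' inner backend, so sub-tree jobs spawn their own block jobs.
#'
#' @inheritParams prune_align
#' @param core_size,max_block_size Block tiling parameters ([tile_blocks]).
#' @param anchor_k k-mer size for anchor constraint generation.
#' @return An [msa] over the leaves, rows in input order.
#' @export
meta_align <- function(seqs, tree, M, core_size, max_block_size = Inf,
                       backend = builtin_backend(),
                       inference = c("maximal", "nearest_leaf"),
                       use_outgroups = FALSE,
                       anchor_k = 12L,
                       mode = c("serial", "parallel"), workers = 1L) {
  inference <- match.arg(inference)
  mode <- match.arg(mode)
  inner <- resolve_backend(backend)
  crumble_wrapped <- as_checked_backend(function(sub, guide_tree = NULL) {
    cs <- generate_anchor_constraints(sub, k = anchor_k)
    block_backend <- function(bs, gt2 = NULL) {
      gt3 <- if (!is.null(guide_tree) && length(bs) > 1L &&
                 all(names(bs) %in% guide_tree$tip.label) && length(bs) >= 2L) {
        if (length(setdiff(guide_tree$tip.label, names(bs))) > 0L) {
          tr <- ape::keep.tip(guide_tree, names(bs))
          if (ape::is.binary(tr) && ape::is.rooted(tr)) tr else NULL
        } else guide_tree
      } else NULL
      inner(bs, gt3)
    }
    crumble_align(sub, cs, backend = block_backend, core_size = core_size,
                  max_block_size = max_block_size, mode = "serial")
  })
  prune_align(seqs, tree, M, backend = crumble_wrapped, inference = inference,
              use_outgroups = use_outgroups, mode = mode, workers = workers)
}
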