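#' Minimum-stage decomposition of a rooted binary phylogeny
#'
#' Breaks the tree into sub-trees that overlap at cut nodes, minimizing the
#' number of sequential stages while capping the number of sequences per
#' sub-tree problem at `M` (leaves plus inferred child-root sequences; an
#' out-group does not count). The recurrence: a single leaf costs one stage
#' (extracting a sequence is counted as a stage); presenting `j >= 2`
#' sequences from a clade splits `j` over the two children; rooting a
#' sub-tree at a node costs one more stage than the best split of at most
#' `M` sequences over its children. Dynamic programming is linear in the
#' leaf count for fixed `M`; ties break toward the smallest left share.
#'
#' @param tree Rooted binary `phylo`.
#' @param M Maximum sequences per sub-tree problem (>= 2).
#' @return A `decomposition`: list with `stage_count`, `problems` (each a
#'   list with `root` node id, `members` — in post-order, each
#'   `list(type = "leaf"|"subroot", id)` — and `stage`), `M`, and `tree`.
#' @export
min_stage_decomposition <- function(tree, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop_input("M must be >= 2 (infeasible otherwise)")
  if (!inherits(tree, "phylo")) stop_input("tree must be a phylo object")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop_input("tree must be rooted and binary (resolve polytomies upstream)")
  }
  ntip <- length(tree$tip.label)
  if (ntip == 1L) stop_input("tree must have at least 2 leaves")
  kids <- children_list(tree)
  nn <- max(tree$edge)
  root <- ntip + 1L
  INF <- .Machine$integer.max %/% 4L
  A <- matrix(INF, nrow = nn, ncol = M)      # A[i, j]: clade i presents j seqs
  splitA <- matrix(NA_integer_, nrow = nn, ncol = M)  # left share for A[i, j>=2]
  rootsplit <- matrix(NA_integer_, nrow = nn, ncol = 2L)  # (jl, jr) for rooted case
  A[seq_len(ntip), 1L] <- 1L
  # post-order over internal nodes: children before parents
  post <- internal_postorder(tree, kids, root)
  for (i in post) {
    l <- kids[[i]][1L]; r <- kids[[i]][2L]
    # rooted at i: split at most M over the children, one extra stage
    best <- INF; bl <- NA_integer_
    for (jl in seq_len(M - 1L)) {
      for (jr in seq_len(M - jl)) {
        v <- max(A[l, jl], A[r, jr])
        if (v < best) { best <- v; bl <- jl; rootsplit[i, ] <- c(jl, jr) }
      }
    }
    A[i, 1L] <- best + 1L
    # unrooted: present j >= 2 sequences, split exactly j over the children
    for (j in 2:M) {
      bestj <- INF; blj <- NA_integer_
      for (jl in seq_len(j - 1L)) {
        v <- max(A[l, jl], A[r, j - jl])
        if (v < bestj) { bestj <- v; blj <- jl }
      }
      A[i, j] <- bestj
      splitA[i, j] <- blj
    }
  }
  problems <- list()
  # expand(node, j): frontier members contributed by clade `node` under a
  # budget of j sequences; returns list(members, stage)
  expand <- function(node, j) {
    if (j == 1L) {
      if (node <= ntip) {
        return(list(members = list(list(type = "leaf", id = node)), stage = 1L))
      }
      pid <- collect(node)
      return(list(members = list(list(type = "subroot", id = node)),
                  stage = problems[[pid]]$stage))
    }
    l <- kids[[node]][1L]; r <- kids[[node]][2L]
    jl <- splitA[node, j]
    L <- expand(l, jl); R <- expand(r, j - jl)
    list(members = c(L$members, R$members), stage = max(L$stage, R$stage))
  }
  # collect(node): emit the sub-tree problem rooted at `node`; returns index
  collect <- function(node) {
    l <- kids[[node]][1L]; r <- kids[[node]][2L]
    jl <- rootsplit[node, 1L]; jr <- rootsplit[node, 2L]
    L <- expand(l, jl); R <- expand(r, jr)
    problems[[length(problems) + 1L]] <<- list(
      root = node,
      members = c(L$members, R$members),
      stage = max(L$stage, R$stage) + 1L)
    length(problems)
  }
  collect(root)
  S <- A[root, 1L]
  stopifnot(problems[[length(problems)]]$stage == S)
  structure(list(tree = tree, M = M, stage_count = S, problems = problems),
            class = "decomposition")
}

internal_postorder <- function(tree, kids, root) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(nd, out)
    for (k in kids[[nd]]) if (k > ntip) stack <- c(stack, k)
  }
  out
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition: %d sub-trees, %d stages (M = %d)\n",
              length(x$problems), x$stage_count, x$M))
  invisible(x)
}

#' Majority-consensus root inference
#'
#' Assigns each alignment column its most frequent non-gap base (ties break
#' A < C < G < T < N), inferring the longest root sequence that fits within
#' the alignment: the output length equals the column count.
#'
#' @param aln An [msa] with at least one row and no all-gap columns.
#' @return The inferred root sequence (character scalar).
#' @export
infer_root_maximal <- function(aln) {
  if (length(aln) < 1L) stop_input("alignment has no rows")
  m <- msa_matrix(aln)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != GAP]
    if (length(col) == 0L) stop_input("all-gap column in alignment")
    counts <- table(factor(col, levels = DNA_ALPHABET))
    DNA_ALPHABET[which.max(counts)]
  }, "") |> collapse()
}

#' Select an out-group leaf for a sub-tree
#'
#' Among the leaves not descended from the sub-tree root, returns the one
#' with the smallest branch-length path to that root (ties break by leaf
#' name); `NULL` when the sub-tree is the whole tree.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param sub_root Node id of the sub-tree root.
#' @param dists Optional precomputed [ape::dist.nodes] matrix.
#' @return Leaf name or `NULL`.
#' @export
select_outgroup <- function(tree, sub_root, dists = NULL) {
  ntip <- length(tree$tip.label)
  if (sub_root == ntip + 1L) return(NULL)
  inside <- clade_tips(tree, sub_root)
  outside <- setdiff(seq_len(ntip), inside)
  if (length(outside) == 0L) return(NULL)
  if (is.null(dists)) dists <- ape::dist.nodes(tree)
  d <- dists[outside, sub_root]
  nms <- tree$tip.label[outside]
  o <- order(d, nms)
  nms[o[1L]]
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd <= ntip) out <- c(out, nd) else stack <- c(stack, kids[[nd]])
  }
  sort(out)
}

#' Merge child alignments into a parent alignment along guide rows
#'
#' Each guide row of the parent is the inferred root of a child alignment;
#' its j-th residue corresponds to child column `map[j]` (strictly
#' increasing). Parent columns receive the mapped child columns; where a
#' guide row is gapped its child rows receive gaps; child columns never hit
#' by the guide (possible with leaf-sequence guides) are inserted as
#' all-others-gap columns immediately before the next mapped column, or
#' appended. Guide rows are replaced by their child's rows in place (kept
#' when `keep_guides`).
#'
#' @param parent An [msa] containing the guide rows.
#' @param guides Named list (names = guide row names); each element
#'   `list(child = msa, map = integer vector, 1-based child columns)`.
#' @param keep_guides Keep the guide rows in the output.
#' @return The merged [msa]; attribute `parent_columns` gives the output
#'   column index of each parent column.
#' @export
merge_alignments <- function(parent, guides, keep_guides = FALSE) {
  if (length(guides) == 0L) return(parent)
  if (!all(names(guides) %in% names(parent))) {
    stop_input("guide rows missing from parent alignment")
  }
  pm <- msa_matrix(parent)
  pc <- ncol(pm)
  for (g in names(guides)) {
    map <- guides[[g]]$map
    child <- guides[[g]]$child
    if (any(diff(map) <= 0L) && length(map) > 1L) {
      stop_internal("guide map for '", g, "' is not strictly increasing")
    }
    if (length(map) > 0L && (min(map) < 1L || max(map) > msa_ncol(child))) {
      stop_internal("guide map for '", g, "' exceeds child columns")
    }
    nres <- sum(pm[g, ] != GAP)
    if (nres != length(map)) {
      stop_internal("guide row '", g, "' has ", nres,
                    " residues but map length ", length(map))
    }
  }
  cms <- lapply(guides, function(x) msa_matrix(x$child))
  # residue counter per guide row as we scan parent columns
  res_i <- setNames(rep(0L, length(guides)), names(guides))
  nxt <- setNames(rep(1L, length(guides)), names(guides))
  out_names <- character(0)
  for (nm in rownames(pm)) {
    if (nm %in% names(guides)) {
      if (keep_guides) out_names <- c(out_names, nm)
      out_names <- c(out_names, rownames(cms[[nm]]))
    } else {
      out_names <- c(out_names, nm)
    }
  }
  if (anyDuplicated(out_names)) stop_internal("duplicate row names after merge")
  cols <- vector("list", 0L)
  parent_columns <- integer(pc)
  emit <- function(col) cols[[length(cols) + 1L]] <<- col
  blank <- setNames(rep(GAP, length(out_names)), out_names)
  child_col <- function(g, j) {
    col <- blank
    col[rownames(cms[[g]])] <- cms[[g]][, j]
    col
  }
  for (c0 in seq_len(pc)) {
    # first flush unmapped child columns due before this parent column
    col <- blank
    for (g in names(guides)) {
      if (pm[g, c0] != GAP) {
        res_i[g] <- res_i[g] + 1L
        mc <- guides[[g]]$map[res_i[g]]
        while (nxt[g] < mc) {
          emit(child_col(g, nxt[g]))
          nxt[g] <- nxt[g] + 1L
        }
        col[rownames(cms[[g]])] <- cms[[g]][, mc]
        if (keep_guides) col[g] <- pm[g, c0]
        nxt[g] <- mc + 1L
      } else if (keep_guides) {
        col[g] <- pm[g, c0]
      }
    }
    for (nm in setdiff(rownames(pm), names(guides))) col[nm] <- pm[nm, c0]
    emit(col)
    parent_columns[c0] <- length(cols)
  }
  for (g in names(guides)) {
    while (nxt[g] <= ncol(cms[[g]])) {
      emit(child_col(g, nxt[g]))
      nxt[g] <- nxt[g] + 1L
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- out_names
  # all-gap columns cannot arise: every emitted column holds a child or
  # parent residue
  out <- msa_from_matrix(m, drop_allgap = FALSE, check = FALSE)
  attr(out, "parent_columns") <- parent_columns
  out
}
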