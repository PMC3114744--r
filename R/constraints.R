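#' Sparse pairwise alignment constraints
#'
#' A constraint aligns one base position of one sequence with one base
#' position of another. A set of such constraints is a *sparse alignment*:
#' it induces a partial order on all residue positions in which aligned
#' positions are equal and positions along one sequence increase. All
#' coordinates are 0-based; intervals elsewhere in the package are half-open
#' `[start, end)`.
#'
#' Constraints are stored symmetric (unordered pairs) and deduplicated, in a
#' canonical orientation: `seq_a` lexicographically before `seq_b`.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param constraints Data frame with columns `seq_a`, `pos_a`, `seq_b`,
#'   `pos_b` (0-based integer positions).
#' @return An object of class `constraint_set` with elements `seqs`,
#'   `lens`, `constraints` plus internal indexes.
#' @export
constraint_set <- function(seqs, constraints = empty_constraint_frame()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_input("sequences must carry unique names")
  }
  check_dna(seqs)
  lens <- setNames(nchar(seqs), names(seqs))
  df <- as.data.frame(constraints, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    need <- c("seq_a", "pos_a", "seq_b", "pos_b")
    if (!all(need %in% names(df))) stop_input("constraint frame needs columns ", collapse(need))
    df$pos_a <- as.integer(df$pos_a)
    df$pos_b <- as.integer(df$pos_b)
    unknown <- setdiff(c(df$seq_a, df$seq_b), names(seqs))
    if (length(unknown) > 0L) stop_input("constraint names unknown sequence: ", collapse(unknown))
    if (any(df$seq_a == df$seq_b)) stop_input("constraint joins a sequence to itself")
    bad <- df$pos_a < 0L | df$pos_b < 0L |
      df$pos_a >= lens[df$seq_a] | df$pos_b >= lens[df$seq_b]
    if (any(bad)) stop_input("constraint position out of range")
    flip <- df$seq_a > df$seq_b
    df[flip, c("seq_a", "pos_a", "seq_b", "pos_b")] <-
      df[flip, c("seq_b", "pos_b", "seq_a", "pos_a")]
    df <- unique(df[order(df$seq_a, df$pos_a, df$seq_b, df$pos_b), , drop = FALSE])
    rownames(df) <- NULL
  }
  cs <- structure(list(seqs = seqs, lens = lens, constraints = df),
                  class = "constraint_set")
  cs$index <- build_cs_index(cs)
  cs
}

empty_constraint_frame <- function() {
  data.frame(seq_a = character(), pos_a = integer(),
             seq_b = character(), pos_b = integer(), stringsAsFactors = FALSE)
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: %d sequences (%d residues), %d constraints\n",
              length(x$seqs), sum(x$lens), nrow(x$constraints)))
  invisible(x)
}

# Per-sequence adjacency (both orientations), sorted by own position, plus
# union-find equivalence classes over constrained positions (global 0-based
# ids: offset[seq] + pos).
build_cs_index <- function(cs) {
  nms <- names(cs$seqs)
  n <- length(nms)
  offs <- setNames(c(0L, cumsum(as.integer(cs$lens))[-n]), nms)
  df <- cs$constraints
  idx <- list(offsets = offs, n = n, names = nms,
              by_seq = vector("list", n))
  names(idx$by_seq) <- nms
  ia <- match(df$seq_a, nms); ib <- match(df$seq_b, nms)
  pos_own <- c(df$pos_a, df$pos_b)
  seq_own <- c(ia, ib)
  seq_oth <- c(ib, ia)
  pos_oth <- c(df$pos_b, df$pos_a)
  for (i in seq_len(n)) {
    sel <- which(seq_own == i)
    o <- sel[order(pos_own[sel])]
    idx$by_seq[[i]] <- list(pos = pos_own[o], other = seq_oth[o], opos = pos_oth[o])
  }
  # union-find over constrained global ids
  gid_a <- offs[df$seq_a] + df$pos_a
  gid_b <- offs[df$seq_b] + df$pos_b
  ids <- sort(unique(c(gid_a, gid_b)))
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ka <- match(gid_a, ids); kb <- match(gid_b, ids)
  for (j in seq_along(ka)) {
    ra <- find(ka[j]); rb <- find(kb[j])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(ids), find, 0L)
  idx$class_ids <- ids          # sorted global ids of constrained positions
  idx$class_of <- root          # class representative index per constrained id
  idx
}

global_id <- function(idx, seq_i, pos) idx$offsets[[seq_i]] + pos

# class index of a position, or NA if unconstrained
class_index <- function(idx, seq_name, pos) {
  g <- idx$offsets[[seq_name]] + pos
  k <- match(g, idx$class_ids)
  if (is.na(k)) NA_integer_ else idx$class_of[k]
}

# Fixpoint threshold propagation.  up = TRUE: u[i] = least position in
# sequence i reachable-from (i.e. >=) the start position under the partial
# order, NA when none.  up = FALSE: greatest position <= the start position.
closure_thresholds <- function(cs, seq_name, pos, up = TRUE) {
  idx <- cs$index
  n <- idx$n
  lens <- as.integer(cs$lens)
  s0 <- match(seq_name, idx$names)
  if (is.na(s0)) stop_input("unknown sequence: ", seq_name)
  if (pos < 0L || pos >= lens[s0]) stop_input("position out of range: ", seq_name, ":", pos)
  if (up) {
    u <- rep.int(NA_integer_, n)
    scanned <- lens            # nothing scanned yet: scan window is [u, scanned)
    u[s0] <- pos
    queue <- s0
    while (length(queue) > 0L) {
      i <- queue[[1L]]; queue <- queue[-1L]
      if (is.na(u[i]) || u[i] >= scanned[i]) next
      bs <- idx$by_seq[[i]]
      lo <- findInterval(u[i] - 0.5, bs$pos) + 1L
      hi <- findInterval(scanned[i] - 0.5, bs$pos)
      scanned[i] <- u[i]
      if (lo > hi) next
      sel <- lo:hi
      for (j in unique(bs$other[sel])) {
        q <- min(bs$opos[sel][bs$other[sel] == j])
        if (is.na(u[j]) || q < u[j]) {
          u[j] <- q
          queue <- c(queue, j)
        }
      }
    }
    setNames(u, idx$names)
  } else {
    d <- rep.int(NA_integer_, n)
    scanned <- rep.int(-1L, n)  # scan window is (scanned, d]
    d[s0] <- pos
    queue <- s0
    while (length(queue) > 0L) {
      i <- queue[[1L]]; queue <- queue[-1L]
      if (is.na(d[i]) || d[i] <= scanned[i]) next
      bs <- idx$by_seq[[i]]
      lo <- findInterval(scanned[i] + 0.5, bs$pos) + 1L
      hi <- findInterval(d[i] + 0.5, bs$pos)
      scanned[i] <- d[i]
      if (lo > hi) next
      sel <- lo:hi
      for (j in unique(bs$other[sel])) {
        q <- max(bs$opos[sel][bs$other[sel] == j])
        if (is.na(d[j]) || q > d[j]) {
          d[j] <- q
          queue <- c(queue, j)
        }
      }
    }
    setNames(d, idx$names)
  }
}

#' Check that a constraint set induces a partial order
#'
#' The set is consistent when the graph whose nodes are equivalence classes
#' of aligned positions, with a directed edge for each within-sequence
#' adjacency between constrained positions, is acyclic — and no class holds
#' two positions of the same sequence.
#'
#' @param cs A [constraint_set].
#' @return List with `consistent` (logical) and `violations` (the rows of
#'   `cs$constraints` implicated in a cycle or same-sequence collapse).
#' @export
check_consistency <- function(cs) {
  idx <- cs$index
  df <- cs$constraints
  if (nrow(df) == 0L) {
    return(list(consistent = TRUE, violations = df))
  }
  ids <- idx$class_ids
  cls <- idx$class_of
  # which sequence each constrained id belongs to
  seq_of <- findInterval(ids, unname(idx$offsets))
  bad_class <- integer(0)
  # same-sequence collapse: one class, two positions of one sequence
  key <- paste(cls, seq_of)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  bad_class <- unique(cls[dup])
  # class DAG from within-sequence adjacency of constrained positions
  ord <- order(seq_of, ids)
  from <- cls[ord][-length(ord)]
  to <- cls[ord][-1L]
  same <- seq_of[ord][-length(ord)] == seq_of[ord][-1L]
  from <- from[same]; to <- to[same]
  keep <- from != to
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from[keep]), to = as.character(to[keep])),
    vertices = data.frame(name = as.character(unique(cls)))
  )
  cyclic_class <- integer(0)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    big <- which(tabulate(comp$membership) > 1L)
    cyclic_class <- as.integer(igraph::V(g)$name[comp$membership %in% big])
  }
  offenders <- union(bad_class, cyclic_class)
  if (length(offenders) == 0L) {
    return(list(consistent = TRUE, violations = df[0L, , drop = FALSE]))
  }
  gid_a <- idx$offsets[df$seq_a] + df$pos_a
  gid_b <- idx$offsets[df$seq_b] + df$pos_b
  ca <- cls[match(gid_a, ids)]
  cb <- cls[match(gid_b, ids)]
  hit <- ca %in% offenders | cb %in% offenders
  list(consistent = FALSE, violations = df[hit, , drop = FALSE])
}

#' Order two positions under the constraint partial order
#'
#' @param cs A consistent [constraint_set].
#' @param p,q Positions as `list(name, index)` or length-2 vectors
#'   (`c("seqA", 3)`), 0-based.
#' @return One of `"before"`, `"after"`, `"equal"`, `"incomparable"`.
#' @export
precedes <- function(cs, p, q) {
  p <- as_position(cs, p); q <- as_position(cs, q)
  if (p$name == q$name) {
    return(if (p$pos < q$pos) "before" else if (p$pos > q$pos) "after" else "equal")
  }
  cp <- class_index(cs$index, p$name, p$pos)
  cq <- class_index(cs$index, q$name, q$pos)
  if (!is.na(cp) && !is.na(cq) && cp == cq) return("equal")
  u <- closure_thresholds(cs, p$name, p$pos, up = TRUE)
  uq <- u[[q$name]]
  if (!is.na(uq) && q$pos >= uq) return("before")
  d <- closure_thresholds(cs, p$name, p$pos, up = FALSE)
  dq <- d[[q$name]]
  if (!is.na(dq) && q$pos <= dq) return("after")
  "incomparable"
}

as_position <- function(cs, p) {
  if (is.list(p)) {
    nm <- as.character(p[[1L]]); pos <- as.integer(p[[2L]])
  } else {
    nm <- as.character(p[[1L]]); pos <- as.integer(p[[2L]])
  }
  if (!nm %in% names(cs$seqs)) stop_input("unknown sequence: ", nm)
  if (is.na(pos) || pos < 0L || pos >= cs$lens[[nm]]) {
    stop_input("position out of range: ", nm, ":", pos)
  }
  list(name = nm, pos = pos)
}
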