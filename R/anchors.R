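#' Generate pairwise constraints from unique k-mer anchors
#'
#' A stand-in constraint generator: for every sequence pair, exact-match
#' k-mers that occur exactly once in both sequences are collected, chained
#' to a maximal non-crossing subset (longest increasing subsequence on the
#' partner offsets, then a greedy non-overlap pass), and expanded to
#' per-base constraints. If pooling the pairs produces a globally
#' inconsistent set, violating constraints are greedily dropped —
#' lowest-multiplicity first (fewest co-violating constraints sharing an
#' equivalence class), ties by lexicographic constraint order — until the
#' set induces a partial order. `N` participates in anchors only as an
#' exact match (`N == N`).
#'
#' @param seqs Named character vector of >= 2 DNA sequences.
#' @param k Anchor k-mer size (>= 4).
#' @param max_anchors_per_pair Cap on chained anchors per pair (evenly
#'   subsampled when exceeded).
#' @return A consistent [constraint_set].
#' @export
generate_anchor_constraints <- function(seqs, k = 12L, max_anchors_per_pair = Inf) {
  if (length(seqs) < 2L) stop_input("need at least 2 sequences")
  k <- as.integer(k)
  if (is.na(k) || k < 4L) stop_input("k must be >= 4")
  check_dna(seqs)
  nms <- names(seqs)
  kpos <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(integer(0))
    km <- substring(s, 1:(L - k + 1L), k:L)
    tab <- table(km)
    uniq <- names(tab)[tab == 1L]
    setNames(match(uniq, km) - 1L, uniq)  # 0-based start offsets
  })
  rows <- list()
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      shared <- intersect(names(kpos[[i]]), names(kpos[[j]]))
      if (length(shared) == 0L) next
      a <- unname(kpos[[i]][shared]); b <- unname(kpos[[j]][shared])
      o <- order(a)
      a <- a[o]; b <- b[o]
      keep <- lis_indices(b)
      a <- a[keep]; b <- b[keep]
      # greedy non-overlap pass so expanded anchors never double-constrain
      sel <- logical(length(a))
      last_a <- last_b <- -k
      for (t in seq_along(a)) {
        if (a[t] >= last_a + k && b[t] >= last_b + k) {
          sel[t] <- TRUE
          last_a <- a[t]; last_b <- b[t]
        }
      }
      a <- a[sel]; b <- b[sel]
      if (is.finite(max_anchors_per_pair) && length(a) > max_anchors_per_pair) {
        pick <- unique(round(seq(1L, length(a), length.out = max_anchors_per_pair)))
        a <- a[pick]; b <- b[pick]
      }
      if (length(a) > 0L) {
        off <- rep(0:(k - 1L), times = length(a))
        rows[[length(rows) + 1L]] <- data.frame(
          seq_a = nms[i], pos_a = rep(a, each = k) + off,
          seq_b = nms[j], pos_b = rep(b, each = k) + off,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else empty_constraint_frame()
  cs <- constraint_set(seqs, df)
  repeat {
    chk <- check_consistency(cs)
    if (chk$consistent) return(cs)
    cs <- drop_one_violation(cs, chk$violations)
  }
}

# longest strictly increasing subsequence: indices, deterministic
# (leftmost optimum)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(0)   # index of smallest tail of an LIS of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    vals <- x[tails]
    pos <- findInterval(x[i] - 0.5, vals) + 1L
    prev[i] <- if (pos > 1L) tails[pos - 1L] else 0L
    tails[pos] <- i
  }
  out <- integer(length(tails))
  cur <- tails[length(tails)]
  for (t in rev(seq_along(tails))) {
    out[t] <- cur
    cur <- prev[cur]
  }
  out
}

# drop the violating constraint with the fewest co-violators in its
# equivalence class group, ties by lexicographic order (the frame is
# already canonically sorted)
drop_one_violation <- function(cs, viol) {
  idx <- cs$index
  ga <- idx$offsets[viol$seq_a] + viol$pos_a
  gb <- idx$offsets[viol$seq_b] + viol$pos_b
  ca <- idx$class_of[match(ga, idx$class_ids)]
  cb <- idx$class_of[match(gb, idx$class_ids)]
  tab <- table(c(ca, cb))
  mult <- as.integer(tab[as.character(ca)]) + as.integer(tab[as.character(cb)])
  drop_row <- viol[order(mult)[1L], , drop = FALSE]
  df <- cs$constraints
  hit <- df$seq_a == drop_row$seq_a & df$pos_a == drop_row$pos_a &
    df$seq_b == drop_row$seq_b & df$pos_b == drop_row$pos_b
  constraint_set(cs$seqs, df[!hit, , drop = FALSE])
}
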