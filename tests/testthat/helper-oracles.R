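# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's internal algorithms: reachability is computed on an
# explicit position graph, decompositions by exhaustive enumeration, optimal
# alignment scores by enumerating alignments, and HKY transition
# probabilities from the closed-form solution.

# ---- position-poset oracle -------------------------------------------------

# boolean reachability matrix over all residue positions; edges are
# within-sequence successors (strict) plus constraint pairs (both ways)
oracle_reach_matrix <- function(cs) {
  lens <- cs$lens
  nms <- names(lens)
  offs <- setNames(c(0L, cumsum(as.integer(lens))[-length(lens)]), nms)
  n <- sum(lens)
  M <- diag(n) > 0
  for (s in nms) {
    if (lens[[s]] > 1L) {
      for (p in seq_len(lens[[s]] - 1L)) {
        M[offs[[s]] + p, offs[[s]] + p + 1L] <- TRUE
      }
    }
  }
  df <- cs$constraints
  for (r in seq_len(nrow(df))) {
    a <- offs[[df$seq_a[r]]] + df$pos_a[r] + 1L
    b <- offs[[df$seq_b[r]]] + df$pos_b[r] + 1L
    M[a, b] <- TRUE
    M[b, a] <- TRUE
  }
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) break
    M <- M2
  }
  list(M = M, offs = offs, lens = lens)
}

oracle_consistent <- function(cs) {
  r <- oracle_reach_matrix(cs)
  for (s in names(r$lens)) {
    L <- r$lens[[s]]
    if (L < 2L) next
    for (p in seq_len(L - 1L)) {
      for (q in (p + 1L):L) {
        if (r$M[r$offs[[s]] + q, r$offs[[s]] + p]) return(FALSE)
      }
    }
  }
  TRUE
}

oracle_precedes <- function(r, cs, p, q) {
  gi <- r$offs[[p[[1L]]]] + as.integer(p[[2L]]) + 1L
  gj <- r$offs[[q[[1L]]]] + as.integer(q[[2L]]) + 1L
  fwd <- r$M[gi, gj]; bwd <- r$M[gj, gi]
  if (fwd && bwd) {
    if (gi == gj) "equal" else "equal"
  } else if (fwd) "before" else if (bwd) "after" else "incomparable"
}

oracle_separation <- function(r, cs, anchor) {
  gi <- r$offs[[anchor[[1L]]]] + as.integer(anchor[[2L]]) + 1L
  start <- end <- setNames(integer(length(r$lens)), names(r$lens))
  for (s in names(r$lens)) {
    L <- r$lens[[s]]
    gpos <- r$offs[[s]] + seq_len(L)
    strictly_below <- r$M[gpos, gi] & !r$M[gi, gpos]
    at_or_after <- r$M[gi, gpos]
    start[s] <- sum(strictly_below)              # prefix property holds
    end[s] <- if (any(at_or_after)) which(at_or_after)[1L] else L
  }
  list(start = start, end = end)
}

# random consistent constraint set: subset of a random gapped alignment
random_truth_cs <- function(nseq, ncol, gap_prob, fraction, seed) {
  set.seed(seed)
  nms <- paste0("s", seq_len(nseq))
  repeat {
    m <- matrix(sample(c("A", "C", "G", "T"), nseq * ncol, replace = TRUE),
                nrow = nseq, dimnames = list(nms, NULL))
    m[matrix(runif(nseq * ncol) < gap_prob, nrow = nseq)] <- "-"
    keep <- colSums(m != "-") > 0
    m <- m[, keep, drop = FALSE]
    if (all(rowSums(m != "-") > 0)) break
  }
  aln <- msa(setNames(apply(m, 1L, paste0, collapse = ""), nms))
  ts <- list(seqs = msa_project(aln), truth = aln)
  constraints_from_truth(ts, fraction = fraction, seed = seed + 1L)
}

# ---- decomposition oracle --------------------------------------------------

# all rooted binary tree shapes with n leaves (unlabeled), as phylo objects
all_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1L) return(list("L"))
    out <- list()
    for (kl in seq_len(k %/% 2L)) {
      for (a in shapes(kl)) for (b in shapes(k - kl)) {
        out[[length(out) + 1L]] <- list(a, b)
      }
    }
    unique(out)
  }
  lapply(shapes(n), function(sh) {
    i <- 0L
    render <- function(x) {
      if (identical(x, "L")) {
        i <<- i + 1L
        return(paste0("t", i, ":1"))
      }
      paste0("(", render(x[[1L]]), ",", render(x[[2L]]), "):1")
    }
    txt <- paste0(sub(":1$", "", render(sh)), ";")
    ape::read.tree(text = txt)
  })
}

# exhaustive minimum stage count over all valid decompositions
oracle_min_stages <- function(tree, M) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  }
  internal <- setdiff(seq_len(nn), seq_len(ntip))
  root <- ntip + 1L
  others <- setdiff(internal, root)
  best <- Inf
  for (mask in 0:(2^length(others) - 1L)) {
    cuts <- c(root, others[bitwAnd(bitwShiftR(mask, seq_along(others) - 1L), 1L) == 1L])
    frontier <- function(node) {      # members seen by the problem at a cut
      out <- list()
      for (ch in kids[[node]]) {
        if (ch <= ntip) out[[length(out) + 1L]] <- c("leaf", ch)
        else if (ch %in% cuts) out[[length(out) + 1L]] <- c("cut", ch)
        else out <- c(out, frontier(ch))
      }
      out
    }
    ok <- TRUE
    stage_of <- function(cut) {
      fr <- frontier(cut)
      if (length(fr) > M) { ok <<- FALSE; return(Inf) }
      1 + max(vapply(fr, function(m) {
        if (m[1L] == "leaf") 1 else stage_of(as.integer(m[2L]))
      }, 0))
    }
    s <- stage_of(root)
    if (ok) best <- min(best, s)
  }
  as.integer(best)
}

# msa content comparison ignoring auxiliary attributes
msa_chars <- function(aln) {
  x <- unclass(aln)
  attributes(x) <- list(names = names(x))
  x
}

# ---- alignment oracles -----------------------------------------------------

# optimal affine-gap global alignment score by enumerating all alignments
oracle_best_pair_score <- function(a, b, params) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  score_alignment <- function(ra, rb) {
    sc <- 0; run_a <- 0L; run_b <- 0L
    for (t in seq_along(ra)) {
      if (ra[t] == "-") {
        run_a <- run_a + 1L; run_b <- 0L
        sc <- sc + if (run_a == 1L) params$gap_open else params$gap_extend
      } else if (rb[t] == "-") {
        run_b <- run_b + 1L; run_a <- 0L
        sc <- sc + if (run_b == 1L) params$gap_open else params$gap_extend
      } else {
        run_a <- run_b <- 0L
        sc <- sc + if (ra[t] == rb[t]) params$match else params$mismatch
      }
    }
    sc
  }
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_alignment(ra, rb))
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) rec(i + 1L, j + 1L, c(ra, ca[i]), c(rb, cb[j]))
    if (i <= length(ca)) rec(i + 1L, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb)) rec(i, j + 1L, c(ra, "-"), c(rb, cb[j]))
    invisible(NULL)
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# naive column-by-column expansion oracle for guide-based merging
oracle_merge <- function(parent, guides, keep_guides = FALSE) {
  pm <- do.call(rbind, strsplit(unclass(parent), ""))
  rownames(pm) <- names(parent)
  cms <- lapply(guides, function(g) {
    m <- do.call(rbind, strsplit(unclass(g$child), ""))
    rownames(m) <- names(g$child)
    m
  })
  out_names <- character(0)
  for (nm in rownames(pm)) {
    if (nm %in% names(guides)) {
      if (keep_guides) out_names <- c(out_names, nm)
      out_names <- c(out_names, rownames(cms[[nm]]))
    } else out_names <- c(out_names, nm)
  }
  cols <- list()
  res_i <- setNames(rep(0L, length(guides)), names(guides))
  nxt <- setNames(rep(1L, length(guides)), names(guides))
  blank <- setNames(rep("-", length(out_names)), out_names)
  for (c0 in seq_len(ncol(pm))) {
    col <- blank
    for (g in names(guides)) {
      if (pm[g, c0] != "-") {
        res_i[g] <- res_i[g] + 1L
        mc <- guides[[g]]$map[res_i[g]]
        while (nxt[g] < mc) {
          extra <- blank
          extra[rownames(cms[[g]])] <- cms[[g]][, nxt[g]]
          cols[[length(cols) + 1L]] <- extra
          nxt[g] <- nxt[g] + 1L
        }
        col[rownames(cms[[g]])] <- cms[[g]][, mc]
        if (keep_guides) col[g] <- pm[g, c0]
        nxt[g] <- mc + 1L
      } else if (keep_guides) col[g] <- pm[g, c0]
    }
    for (nm in setdiff(rownames(pm), names(guides))) col[nm] <- pm[nm, c0]
    cols[[length(cols) + 1L]] <- col
  }
  for (g in names(guides)) {
    while (nxt[g] <= ncol(cms[[g]])) {
      extra <- blank
      extra[rownames(cms[[g]])] <- cms[[g]][, nxt[g]]
      cols[[length(cols) + 1L]] <- extra
      nxt[g] <- nxt[g] + 1L
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- out_names
  keep <- colSums(m != "-") > 0
  m <- m[, keep, drop = FALSE]
  msa(setNames(apply(m, 1L, paste0, collapse = ""), out_names))
}

# ---- HKY closed form -------------------------------------------------------

# closed-form HKY transition matrix (Hasegawa-Kishino-Yano), normalized to
# one expected substitution per site per unit time
oracle_hky_P <- function(kappa, freqs, t) {
  bases <- c("A", "C", "G", "T")
  names(freqs) <- bases
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  piR <- freqs[["A"]] + freqs[["G"]]
  piY <- freqs[["C"]] + freqs[["T"]]
  beta <- 1 / (2 * (freqs[["A"]] * freqs[["C"]] + freqs[["A"]] * freqs[["T"]] +
                      freqs[["G"]] * freqs[["C"]] + freqs[["G"]] * freqs[["T"]]) +
                 2 * kappa * (freqs[["A"]] * freqs[["G"]] + freqs[["C"]] * freqs[["T"]]))
  e2 <- exp(-beta * t)
  P <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    grp <- if (purine[[j]]) piR else piY
    e3 <- exp(-beta * t * (1 + grp * (kappa - 1)))
    if (i == j) {
      P[i, j] <- freqs[[j]] + freqs[[j]] * (1 / grp - 1) * e2 + ((grp - freqs[[j]]) / grp) * e3
    } else if (purine[[i]] == purine[[j]]) {  # transition
      P[i, j] <- freqs[[j]] + freqs[[j]] * (1 / grp - 1) * e2 - (freqs[[j]] / grp) * e3
    } else {                                   # transversion
      P[i, j] <- freqs[[j]] * (1 - e2)
    }
  }
  P
}

# ---- misc helpers ----------------------------------------------------------

projections_match <- function(aln, seqs) {
  identical(unname(msa_project(aln)[names(seqs)]), unname(seqs))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sim_instance <- function(leaves, length, tree_len, seed) {
  tr <- random_tree(leaves, tree_len, seed = seed)
  ts <- evolve(tr, sim_config(root_length = length, seed = seed + 1000L))
  ts
}
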