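#' Configuration for neutral sequence-evolution simulation
#'
#' Substitutions follow the HKY model (transition/transversion rate ratio
#' `kappa`, equilibrium base frequencies `freqs`), applied per branch via
#' the matrix exponential of the rate matrix scaled to one expected
#' substitution per site per unit branch length. Insertions and deletions
#' arrive as Poisson counts per branch (`rate * branch_length * length`)
#' with geometric lengths (parameter `indel_p`, mean `1/indel_p`), placed
#' uniformly; deletions are truncated at sequence ends.
#'
#' @param root_length Root sequence length (bp).
#' @param kappa HKY transition/transversion rate ratio (> 0).
#' @param freqs Equilibrium base frequencies (A, C, G, T), positive,
#'   summing to 1.
#' @param ins_rate,del_rate Indel events per site per unit branch length.
#' @param indel_p Geometric length parameter in (0, 1].
#' @param seed Random seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(root_length = 1000L, kappa = 2.0,
                       freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       ins_rate = 0.02, del_rate = 0.02, indel_p = 0.4,
                       seed = 1L) {
  freqs <- unname(freqs)
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop_input("freqs must be 4 positive values summing to 1")
  }
  if (kappa <= 0) stop_input("kappa must be > 0")
  if (ins_rate < 0 || del_rate < 0) stop_input("indel rates must be >= 0")
  if (indel_p <= 0 || indel_p > 1) stop_input("indel_p must be in (0, 1]")
  structure(list(root_length = as.integer(root_length), kappa = kappa,
                 freqs = setNames(freqs, DNA_BASES),
                 ins_rate = ins_rate, del_rate = del_rate,
                 indel_p = indel_p, seed = as.integer(seed)),
            class = "sim_config")
}

# HKY rate matrix normalized to one expected substitution per site per unit
# time; rows/cols in A, C, G, T order
hky_rate_matrix <- function(kappa, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- freqs[j]
    if (any(transitions[, 1L] == DNA_BASES[i] & transitions[, 2L] == DNA_BASES[j])) {
      rate <- rate * kappa
    }
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# substitution probability matrix over a branch
hky_transition_matrix <- function(kappa, freqs, t) {
  Q <- hky_rate_matrix(kappa, freqs)
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  P
}

#' Random rooted binary tree (Yule process)
#'
#' Grows a topology by uniformly splitting a random extant leaf; branch
#' lengths are exponential, rescaled so their sum equals `total_length`.
#'
#' @param n Leaf count (>= 2).
#' @param total_length Total tree length (substitutions/site).
#' @param seed Random seed.
#' @return Rooted binary `phylo` with tips `t1..tn`.
#' @export
random_tree <- function(n, total_length = 1.0, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_input("n must be >= 2")
  with_seed(seed, {
    # nodes as a growing list: leaves hold NULL children
    kids <- list(NULL)
    leaves <- 1L
    while (length(leaves) < n) {
      pick <- leaves[sample.int(length(leaves), 1L)]
      a <- length(kids) + 1L; b <- length(kids) + 2L
      kids[[a]] <- NULL; kids[[b]] <- NULL
      length(kids) <- b
      kids[[pick]] <- c(a, b)
      leaves <- c(setdiff(leaves, pick), a, b)
    }
    lens <- rexp(2L * n - 2L)
    lens <- lens * (total_length / sum(lens))
    li <- 0L
    tip <- 0L
    rec <- function(node) {
      if (is.null(kids[[node]])) {
        tip <<- tip + 1L
        return(paste0("t", tip))
      }
      ch <- kids[[node]]
      sa <- rec(ch[1L]); la <- lens[li <<- li + 1L]
      sb <- rec(ch[2L]); lb <- lens[li <<- li + 1L]
      sprintf("(%s:%.12g,%s:%.12g)", sa, la, sb, lb)
    }
    txt <- paste0(rec(1L), ";")
    check_tree(ape::read.tree(text = txt))
  })
}

#' Simulate neutral evolution along a tree with a true alignment
#'
#' The root is drawn from the equilibrium frequencies. Along each branch
#' substitutions are applied per site from the HKY transition matrix at the
#' branch length, then Poisson-count deletions and insertions with
#' geometric lengths. Homology is tracked through unique residue
#' identities, so the returned truth alignment places homologous residues
#' in one column and inserted residues in columns of their own sub-tree.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param config A [sim_config].
#' @return A `truth_set`: list with `tree`, `seqs` (leaf sequences) and
#'   `truth` (the true [msa] over the leaves).
#' @export
evolve <- function(tree, config) {
  check_tree(tree)
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L0 <- config$root_length
    keys <- new.env(parent = emptyenv())
    keys$v <- as.double(seq_len(L0))       # id -> sort key
    new_ids <- function(n, key_lo, key_hi) {
      ids <- seq.int(length(keys$v) + 1L, length.out = n)
      kk <- key_lo + (key_hi - key_lo) * seq_len(n) / (n + 1)
      if (any(duplicated(kk)) || any(kk <= key_lo) || any(kk >= key_hi)) {
        stop_internal("homology key precision exhausted")
      }
      keys$v <- c(keys$v, kk)
      ids
    }
    root_ids <- seq_len(L0)
    root_seq <- sample(DNA_BASES, L0, replace = TRUE, prob = config$freqs)
    kids <- children_list(tree)
    blen <- branch_lengths_by_node(tree)
    ntip <- length(tree$tip.label)
    leaf_state <- vector("list", ntip)
    walk <- function(node, bases, ids) {
      if (node <= ntip) {
        leaf_state[[node]] <<- list(bases = bases, ids = ids)
        return(invisible(NULL))
      }
      for (ch in kids[[node]]) {
        st <- evolve_branch(bases, ids, blen[ch], config, keys, new_ids)
        walk(ch, st$bases, st$ids)
      }
      invisible(NULL)
    }
    walk(ntip + 1L, root_seq, root_ids)
    leaf_names <- tree$tip.label
    seqs <- setNames(vapply(leaf_state, function(s) collapse(s$bases), ""),
                     leaf_names)
    all_ids <- unique(unlist(lapply(leaf_state, `[[`, "ids")))
    all_ids <- all_ids[order(keys$v[all_ids])]
    col_of <- setNames(seq_along(all_ids), all_ids)
    m <- matrix(GAP, nrow = ntip, ncol = length(all_ids),
                dimnames = list(leaf_names, NULL))
    for (i in seq_len(ntip)) {
      m[i, col_of[as.character(leaf_state[[i]]$ids)]] <- leaf_state[[i]]$bases
    }
    structure(list(tree = tree, seqs = seqs, truth = msa_from_matrix(m)),
              class = "truth_set")
  })
}

evolve_branch <- function(bases, ids, t, config, keys, new_ids) {
  L <- length(bases)
  if (t > 0 && L > 0L) {
    P <- hky_transition_matrix(config$kappa, config$freqs, t)
    out <- bases
    for (b in DNA_BASES) {
      sel <- which(bases == b)
      if (length(sel) > 0L) {
        out[sel] <- sample(DNA_BASES, length(sel), replace = TRUE, prob = P[b, ])
      }
    }
    bases <- out
  }
  # deletions then insertions, counts Poisson in the current length
  n_del <- if (config$del_rate > 0 && length(bases) > 0L) {
    rpois(1L, config$del_rate * t * length(bases))
  } else 0L
  for (d in seq_len(n_del)) {
    L <- length(bases)
    if (L == 0L) break
    start <- sample.int(L, 1L)
    len <- 1L + rgeom(1L, config$indel_p)
    stop_at <- min(L, start + len - 1L)
    bases <- bases[-(start:stop_at)]
    ids <- ids[-(start:stop_at)]
  }
  n_ins <- if (config$ins_rate > 0) {
    rpois(1L, config$ins_rate * t * max(1L, length(bases)))
  } else 0L
  for (d in seq_len(n_ins)) {
    L <- length(bases)
    after <- sample.int(L + 1L, 1L) - 1L   # insert after this many residues
    len <- 1L + rgeom(1L, config$indel_p)
    key_lo <- if (after == 0L) {
      if (L == 0L) 0 else keys$v[ids[1L]] - 1
    } else {
      keys$v[ids[after]]
    }
    key_hi <- if (after >= L) {
      if (L == 0L) 1 else keys$v[ids[L]] + 1
    } else {
      keys$v[ids[after + 1L]]
    }
    nid <- new_ids(len, key_lo, key_hi)
    nb <- sample(DNA_BASES, len, replace = TRUE, prob = config$freqs)
    bases <- append(bases, nb, after = after)
    ids <- append(ids, nid, after = after)
  }
  list(bases = bases, ids = ids)
}

#' Sample pairwise constraints from a true alignment
#'
#' Uniformly samples the requested fraction of the truth alignment's
#' residue-residue pairs; any subset of a valid alignment induces a partial
#' order, so the result always passes [check_consistency].
#'
#' @param truth A `truth_set` from [evolve] (or a list with `seqs` and
#'   `truth`).
#' @param fraction Fraction of truth pairs to keep, in (0, 1].
#' @param seed Random seed for the subset.
#' @return A consistent [constraint_set].
#' @export
constraints_from_truth <- function(truth, fraction = 1.0, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop_input("fraction must be in (0, 1]")
  aln <- truth$truth
  nms <- names(aln)
  m <- msa_matrix(aln)
  res_idx <- t(apply(m != GAP, 1L, cumsum)) - 1L  # residue index per cell
  rows <- list()
  for (i in seq_len(length(nms) - 1L)) {
    for (j in (i + 1L):length(nms)) {
      both <- m[i, ] != GAP & m[j, ] != GAP
      if (!any(both)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_a = nms[i], pos_a = res_idx[i, both],
        seq_b = nms[j], pos_b = res_idx[j, both],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else empty_constraint_frame()
  if (fraction < 1 && nrow(df) > 0L) {
    keep <- with_seed(seed, sample.int(nrow(df), max(1L, round(fraction * nrow(df)))))
    df <- df[sort(keep), , drop = FALSE]
  }
  constraint_set(truth$seqs, df)
}
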