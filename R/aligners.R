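#' Alignment scoring parameters
#'
#' Integer scores under a maximization convention; a gap run of length L
#' costs `gap_open + (L - 1) * gap_extend`. Defaults: match 1, mismatch -1,
#' open -2, extend -1.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores;
#'   `gap_open <= 0`, `gap_extend <= 0`.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1L, mismatch = -1L,
                             gap_open = -2L, gap_extend = -1L) {
  if (gap_open > 0 || gap_extend > 0) {
    stop_input("gap penalties must be <= 0 under the maximization convention")
  }
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend)),
            class = "alignment_params")
}

#' Optimal global pairwise alignment with affine gaps
#'
#' @param a,b DNA strings.
#' @param params An [alignment_params].
#' @return List with gapped strings `a`, `b` and the optimal `score`.
#' @export
align_pairwise <- function(a, b, params = alignment_params()) {
  .pair_align_cpp(a, b, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
}

#' Built-in deterministic progressive aligner
#'
#' Aligns sequences by post-order traversal of a guide tree. Each
#' sub-alignment is represented by its nearest leaf (smallest branch-length
#' distance, ties by leaf name); at every internal node the two
#' representative sequences are aligned by optimal pairwise affine-gap DP
#' and the child sub-alignments are spliced under that pairwise alignment,
#' so leaf sequences guide every merge. Without a guide tree one is built
#' by neighbor joining on a normalized shared k-mer distance (k = 6).
#'
#' @param seqs Named character vector of DNA sequences (>= 1).
#' @param guide_tree Optional rooted binary `phylo` whose tips are
#'   `names(seqs)`.
#' @param params An [alignment_params].
#' @return An [msa] with rows in input order.
#' @export
progressive_align <- function(seqs, guide_tree = NULL, params = alignment_params()) {
  if (length(seqs) == 0L) return(msa(character(0)))
  check_dna(seqs)
  if (length(seqs) == 1L) return(msa_trivial(seqs))
  if (is.null(guide_tree)) {
    guide_tree <- kmer_guide_tree(seqs)
  } else {
    check_tree(guide_tree)
    if (!setequal(guide_tree$tip.label, names(seqs))) {
      stop_input("guide tree tips do not match sequence names")
    }
  }
  kids <- children_list(guide_tree)
  blen <- branch_lengths_by_node(guide_tree)
  rec <- function(node) {
    if (node <= length(guide_tree$tip.label)) {
      nm <- guide_tree$tip.label[node]
      return(list(aln = msa_trivial(seqs[nm]), rep = nm, repdist = 0))
    }
    ch <- kids[[node]]
    L <- rec(ch[1L]); R <- rec(ch[2L])
    dl <- L$repdist + blen[ch[1L]]
    dr <- R$repdist + blen[ch[2L]]
    sl <- msa_project(L$aln, L$rep)[[1L]]
    sr <- msa_project(R$aln, R$rep)[[1L]]
    pw <- align_pairwise(sl, sr, params)
    parent <- msa(setNames(c(pw$a, pw$b), c(L$rep, R$rep)), check = FALSE)
    merged <- merge_alignments(parent, guides = setNames(list(
      list(child = L$aln, map = guide_map_from_row(L$aln, L$rep)),
      list(child = R$aln, map = guide_map_from_row(R$aln, R$rep))
    ), c(L$rep, R$rep)))
    pick_l <- dl < dr || (dl == dr && L$rep <= R$rep)
    list(aln = merged,
         rep = if (pick_l) L$rep else R$rep,
         repdist = if (pick_l) dl else dr)
  }
  out <- rec(length(guide_tree$tip.label) + 1L)$aln
  msa(unclass(out)[names(seqs)])
}

# columns (1-based) at which a row carries its residues
guide_map_from_row <- function(aln, row) {
  which(chars(unclass(aln)[[row]]) != GAP)
}

#' The built-in aligner as a pluggable backend
#'
#' A backend is `function(seqs, guide_tree = NULL)` returning an [msa];
#' every backend result is checked against the projection contract (each
#' output row, gaps removed, equals its input sequence).
#'
#' @param params An [alignment_params].
#' @return A backend function.
#' @export
builtin_backend <- function(params = alignment_params()) {
  as_checked_backend(function(seqs, guide_tree = NULL) {
    progressive_align(seqs, guide_tree, params)
  })
}

#' Wrap an external command-line aligner as a backend
#'
#' The template must contain `{in}` and `{out}` placeholders; the input is
#' written as unaligned FASTA, the command is run, and aligned FASTA is read
#' back from the output path. The projection contract is enforced on the
#' result.
#'
#' @param command_template Shell command with `{in}` / `{out}` placeholders.
#' @return A backend function.
#' @export
external_backend <- function(command_template) {
  if (!grepl("{in}", command_template, fixed = TRUE) ||
      !grepl("{out}", command_template, fixed = TRUE)) {
    stop_input("command template must contain {in} and {out} placeholders")
  }
  as_checked_backend(function(seqs, guide_tree = NULL) {
    dir <- tempfile("metalign_ext")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    fin <- file.path(dir, "in.fa"); fout <- file.path(dir, "out.fa")
    write_fasta(seqs, fin)
    cmd <- gsub("{out}", shQuote(fout),
                gsub("{in}", shQuote(fin), command_template, fixed = TRUE),
                fixed = TRUE)
    status <- system(paste(cmd, "2>&1"), intern = FALSE)
    if (!identical(status, 0L)) {
      stop_backend("external aligner exited with status ", status, ": ", cmd)
    }
    if (!file.exists(fout)) stop_backend("external aligner produced no output: ", cmd)
    aln <- tryCatch(read_alignment(fout), error = function(e) {
      stop_backend("external aligner output unparseable: ", conditionMessage(e))
    })
    aln
  })
}

# contract enforcement shared by all backends
as_checked_backend <- function(fn) {
  function(seqs, guide_tree = NULL) {
    if (length(seqs) <= 1L) return(msa_trivial(seqs))
    aln <- fn(seqs, guide_tree)
    if (!setequal(names(aln), names(seqs))) {
      stop_backend("backend row names differ from input names")
    }
    proj <- msa_project(aln)
    if (!identical(unname(proj[names(seqs)]), unname(seqs))) {
      bad <- names(seqs)[proj[names(seqs)] != seqs]
      stop_backend("backend violated the projection contract for: ", collapse(bad))
    }
    aln
  }
}

#' Resolve a backend selection string
#'
#' `"builtin"` selects the built-in progressive aligner; `"cmd:<template>"`
#' wraps an external command (see [external_backend]).
#'
#' @param spec Selection string.
#' @return A backend function.
#' @export
resolve_backend <- function(spec) {
  if (is.function(spec)) return(spec)
  if (identical(spec, "builtin")) return(builtin_backend())
  if (startsWith(spec, "cmd:")) return(external_backend(sub("^cmd:", "", spec)))
  stop_input("unknown backend: ", spec)
}

# neighbor-joining guide tree from normalized shared 6-mer distance
kmer_guide_tree <- function(seqs, k = 6L) {
  n <- length(seqs)
  nms <- names(seqs)
  if (n == 2L) {
    return(check_tree(ape::read.tree(
      text = sprintf("(%s:0.5,%s:0.5);", nms[1L], nms[2L]))))
  }
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- max(1L, min(length(km[[i]]), length(km[[j]])))
      d[i, j] <- d[j, i] <- 1 - length(intersect(km[[i]], km[[j]])) / denom
    }
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr <- ape::root(tr, outgroup = nms[1L], resolve.root = TRUE)
  check_tree(tr)
}

children_list <- function(tree) {
  nn <- max(tree$edge)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  kids
}

branch_lengths_by_node <- function(tree) {
  nn <- max(tree$edge)
  b <- numeric(nn)
  b[tree$edge[, 2L]] <- tree$edge.length
  b
}
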