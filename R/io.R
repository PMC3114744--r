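#' Read unaligned DNA sequences from FASTA
#'
#' Sequences are upper-cased and gap characters are stripped (a pre-aligned
#' file can therefore be fed back in as an unaligned problem).
#'
#' @param path FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  recs <- parse_fasta(path)
  recs <- toupper(gsub(GAP, "", recs, fixed = TRUE))
  check_dna(recs)
  recs
}

#' Write sequences or alignment rows to FASTA
#'
#' @param records Named character vector or `msa`.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  records <- unclass(records)
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop_input("FASTA must start with a header line: ", path)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- vapply(strsplit(names, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(names)) stop_input("duplicate FASTA headers: ", path)
  grp <- cumsum(hdr)
  body <- vapply(split(lines[!hdr], grp[!hdr])[as.character(seq_along(names))],
                 function(x) collapse(gsub("\\s", "", x)), "")
  body[is.na(body)] <- ""
  setNames(as.character(body), names)
}

check_dna <- function(recs) {
  bad <- grepl(sprintf("[^%s]", collapse(DNA_ALPHABET)), recs)
  if (any(bad)) {
    stop_input("non-DNA characters in sequence(s): ", collapse(names(recs)[bad]))
  }
  invisible(recs)
}

#' Read a multiple alignment from aligned FASTA
#'
#' @param path Aligned FASTA file; all rows must be the same length.
#' @return An [msa].
#' @export
read_alignment <- function(path) {
  recs <- toupper(parse_fasta(path))
  w <- nchar(recs)
  if (length(unique(w)) > 1L) stop_input("ragged alignment rows in ", path)
  msa(recs)
}

#' Write a multiple alignment
#'
#' `afa` writes aligned multi-FASTA. `maf` writes a single MAF alignment
#' block with 0-based starts, ungapped source sizes and `+` strands.
#'
#' @param aln An [msa].
#' @param path Output file.
#' @param format `"afa"` or `"maf"`.
#' @export
write_alignment <- function(aln, path, format = c("afa", "maf")) {
  format <- match.arg(format)
  if (format == "afa") return(write_fasta(aln, path))
  proj <- msa_project(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("a score=0.0", con)
  for (nm in names(aln)) {
    writeLines(sprintf("s %s 0 %d + %d %s",
                       nm, nchar(proj[[nm]]), nchar(proj[[nm]]), unclass(aln)[[nm]]), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read / write a rooted binary phylogeny in Newick format
#'
#' Branch lengths are required on every edge; polytomies are rejected
#' (resolve them upstream, e.g. with [ape::multi2di], before use).
#'
#' @param path Newick file.
#' @return An [ape::read.tree] `phylo` object, validated rooted-binary.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop_input("cannot parse Newick file: ", path)
  check_tree(tr)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("not a phylo object")
  if (is.null(tree$edge.length)) stop_input("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop_input("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop_input("duplicate leaf names in tree")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop_input("tree must be rooted and binary (resolve polytomies upstream)")
  }
  tree
}

#' Read / write pairwise position constraints (TSV)
#'
#' One constraint per line: `seq_a<TAB>pos_a<TAB>seq_b<TAB>pos_b` with
#' 0-based residue positions; `#` starts a comment.
#'
#' @param path TSV file.
#' @param seqs Named character vector of the sequences the constraints refer
#'   to (needed to validate ranges and build the [constraint_set]).
#' @return A [constraint_set].
#' @export
read_constraints <- function(path, seqs) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(constraint_set(seqs, empty_constraint_frame()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop_input("malformed constraint line in ", path)
  df <- data.frame(
    seq_a = vapply(parts, `[[`, "", 1L),
    pos_a = as.integer(vapply(parts, `[[`, "", 2L)),
    seq_b = vapply(parts, `[[`, "", 3L),
    pos_b = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$pos_a) || anyNA(df$pos_b)) stop_input("non-integer position in ", path)
  constraint_set(seqs, df)
}

#' @rdname read_constraints
#' @param cs A [constraint_set].
#' @export
write_constraints <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# seq_a\tpos_a\tseq_b\tpos_b (0-based)", con)
  df <- cs$constraints
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%d\t%s\t%d", df$seq_a, df$pos_a, df$seq_b, df$pos_b), con)
  }
  invisible(path)
}
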