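#' Multiple alignment container
#'
#' An `msa` is an ordered set of named rows of equal length over
#' `A,C,G,T,N,-`. Gap removal from any row (its *projection*) must reproduce
#' the source sequence; the container never holds all-gap columns.
#'
#' @param rows Named character vector of gapped strings (upper case).
#' @param check Validate invariants (equal row lengths, alphabet, no all-gap
#'   column).
#' @return An object of class `msa`.
#' @export
msa <- function(rows, check = TRUE) {
  rows <- unlist(rows)
  if (length(rows) == 0L) {
    return(structure(setNames(character(0), character(0)), class = "msa"))
  }
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop_input("alignment rows must be named")
  }
  if (anyDuplicated(names(rows))) {
    stop_input("duplicate row names in alignment")
  }
  storage.mode(rows) <- "character"
  out <- structure(rows, class = "msa")
  if (check) validate_msa(out)
  out
}

validate_msa <- function(aln) {
  if (length(aln) == 0L) return(invisible(aln))
  w <- nchar(unclass(aln))
  if (length(unique(w)) > 1L) {
    stop_input("ragged alignment: row lengths ", paste(unique(w), collapse = ", "))
  }
  if (any(grepl(sprintf("[^%s-]", collapse(DNA_ALPHABET)), unclass(aln)))) {
    stop_input("alignment contains characters outside A,C,G,T,N,-")
  }
  if (w[1L] > 0L) {
    m <- msa_matrix(aln)
    if (any(colSums(m != GAP) == 0L)) stop_input("alignment contains an all-gap column")
  }
  invisible(aln)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", length(x), msa_ncol(x)))
  show <- unclass(x)
  if (msa_ncol(x) > 60L) show <- paste0(substr(show, 1L, 57L), "...")
  for (i in seq_along(show)) cat(sprintf("  %-12s %s\n", names(x)[i], show[i]))
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln An `msa`.
#' @return Integer column count.
#' @export
msa_ncol <- function(aln) {
  if (length(aln) == 0L) return(0L)
  nchar(unclass(aln)[[1L]])
}

#' Project an alignment row back to its sequence
#'
#' @param aln An `msa`.
#' @param name Row name; default all rows.
#' @return Named character vector of ungapped sequences.
#' @export
msa_project <- function(aln, name = names(aln)) {
  rows <- unclass(aln)[name]
  if (anyNA(rows)) stop_input("unknown alignment row: ", collapse(setdiff(name, names(aln))))
  gsub(GAP, "", rows, fixed = TRUE)
}

# character matrix view (rows x columns)
msa_matrix <- function(aln) {
  n <- msa_ncol(aln)
  m <- matrix(GAP, nrow = length(aln), ncol = n, dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) m[i, ] <- chars(unclass(aln)[[i]])
  m
}

msa_from_matrix <- function(m, drop_allgap = TRUE, check = TRUE) {
  if (drop_allgap && ncol(m) > 0L) {
    keep <- colSums(m != GAP) > 0L
    m <- m[, keep, drop = FALSE]
  }
  msa(setNames(apply(m, 1L, collapse), rownames(m)), check = check)
}

# drop all-gap columns from a possibly-degenerate row set
drop_allgap_columns <- function(rows) {
  if (length(rows) == 0L || nchar(rows[[1L]]) == 0L) return(rows)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- colSums(m != GAP) > 0L
  setNames(apply(m[, keep, drop = FALSE], 1L, collapse), names(rows))
}

# column-wise concatenation over a shared species set; species absent from a
# piece contribute gap runs
msa_concat <- function(pieces, species) {
  segs <- lapply(pieces, function(p) {
    w <- msa_ncol(p)
    out <- setNames(rep(strrep(GAP, w), length(species)), species)
    out[names(p)] <- unclass(p)
    out
  })
  rows <- setNames(vapply(species, function(s) {
    collapse(vapply(segs, `[[`, "", s))
  }, ""), species)
  msa(rows)
}

# trivial alignment of 0 or 1 sequences
msa_trivial <- function(seqs) {
  msa(seqs, check = FALSE)
}
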