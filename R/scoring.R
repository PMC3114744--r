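#' Pairwise projection of a multiple alignment
#'
#' The ordered list of events for a species pair: residue i of X aligned to
#' residue j of Y, residue i of X aligned to a gap, or a gap aligned to
#' residue j of Y. Columns gapped in both species are dropped. Residue
#' indices are 0-based.
#'
#' @param aln An [msa].
#' @param X,Y Row names.
#' @return Data frame with integer columns `x`, `y` (`NA` marks the gap
#'   side of an event).
#' @export
project_pair <- function(aln, X, Y) {
  rows <- unclass(aln)[c(X, Y)]
  if (anyNA(rows)) stop_input("unknown alignment row")
  cx <- chars(rows[[1L]]); cy <- chars(rows[[2L]])
  rx <- cx != GAP; ry <- cy != GAP
  keep <- rx | ry
  ix <- cumsum(rx) - 1L
  iy <- cumsum(ry) - 1L
  data.frame(x = ifelse(rx, ix, NA_integer_)[keep],
             y = ifelse(ry, iy, NA_integer_)[keep])
}

pair_event_keys <- function(ev) {
  ifelse(!is.na(ev$x) & !is.na(ev$y), paste0("R", ev$x, ":", ev$y),
         ifelse(!is.na(ev$x), paste0("X", ev$x), paste0("Y", ev$y)))
}

#' Average agreement between a predicted and a true alignment
#'
#' For each species pair, the fraction of the predicted pairwise
#' projection's events (residue-residue matches on both indices, gap events
#' on the residue side) that also occur in the true alignment's projection;
#' averaged over all pairs of species, or over a random sample of pairs.
#' Two identical alignments score 1; two alignments sharing no event score
#' 0. The denominator is the predicted projection's event count, so the
#' score is asymmetric in its arguments by design.
#'
#' @param pred,truth [msa] objects with identical row names and row
#'   projections.
#' @param sample_pairs Optionally score only this many species pairs,
#'   sampled uniformly without replacement.
#' @param seed Seed for pair sampling (required when `sample_pairs` is
#'   given).
#' @return Numeric agreement in `[0, 1]`.
#' @export
agreement <- function(pred, truth, sample_pairs = NULL, seed = NULL) {
  if (!setequal(names(pred), names(truth))) {
    stop_input("row names differ between predicted and true alignment")
  }
  pp <- msa_project(pred)
  tp <- msa_project(truth)[names(pp)]
  if (!identical(unname(pp), unname(tp))) {
    stop_input("row projections differ between predicted and true alignment")
  }
  nms <- sort(names(pred))
  if (length(nms) < 2L) stop_input("need at least two rows to score")
  pairs <- utils::combn(nms, 2L, simplify = FALSE)
  if (!is.null(sample_pairs) && sample_pairs < length(pairs)) {
    if (is.null(seed)) stop_input("seed is required when sampling pairs")
    pairs <- with_seed(seed, sample(pairs, sample_pairs, replace = FALSE))
  }
  scores <- vapply(pairs, function(p) {
    pe <- pair_event_keys(project_pair(pred, p[1L], p[2L]))
    te <- pair_event_keys(project_pair(truth, p[1L], p[2L]))
    if (length(pe) == 0L) return(1)
    mean(pe %in% te)
  }, 0)
  mean(scores)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
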