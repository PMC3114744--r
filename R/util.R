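#' @useDynLib metalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp rgeom rpois runif setNames as.dist
#' @importFrom utils head tail combn
NULL

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")
GAP <- "-"

#' Set or query the logging level
#'
#' Structured progress records (per block / sub-tree: identifiers, residue
#' counts, wall time) are emitted at `"info"` level; job scheduling detail at
#' `"debug"`. The default level `"warn"` keeps the package quiet.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"quiet"`. Missing:
#'   return the current level.
#' @return The current level, invisibly when setting.
#' @export
metalign_log_level <- function(level) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (missing(level)) {
    return(getOption("metalign.log_level", "warn"))
  }
  level <- match.arg(level, names(levels))
  options(metalign.log_level = level)
  invisible(level)
}

log_at <- function(level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  cur <- levels[[getOption("metalign.log_level", "warn")]]
  if (levels[[level]] >= cur) {
    message(sprintf("[metalign %s] %s", level, paste0(...)))
  }
}

stop_input <- function(...) {
  stop(structure(
    class = c("metalign_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_internal <- function(...) {
  stop(structure(
    class = c("metalign_internal_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_backend <- function(...) {
  stop(structure(
    class = c("metalign_backend_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# split a DNA / gapped string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

collapse <- function(x) paste0(x, collapse = "")
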