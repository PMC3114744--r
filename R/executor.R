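#' Hierarchical jobs: children and follow-on
#'
#' A job runs an action which may dynamically create *children* (independent
#' jobs run concurrently in parallel mode) and a *follow-on* job that runs
#' only after the job and all of its descendants have completed
#' successfully. The follow-on receives the job's own value and the final
#' values of its children, and may itself create more children. Each job
#' owns a temporary-directory lifecycle: a scratch dir is created before its
#' action runs and removed once its whole subtree (follow-on included) has
#' completed.
#'
#' @param id Unique job identifier (string).
#' @param action `function(...)` returning either a plain value or a list
#'   created with [job_result()].
#' @param args List of arguments for `action`.
#' @return An object of class `metalign_job`.
#' @export
job <- function(id, action, args = list()) {
  stopifnot(is.character(id), length(id) == 1L, is.function(action))
  structure(list(id = id, action = action, args = args), class = "metalign_job")
}

#' Declare a job action's outcome
#'
#' @param value The job's own value.
#' @param children List of [job]s to run after this job.
#' @param follow_on `function(value, child_values)` returning a [job] to run
#'   after all children (and their descendants) complete, or `NULL`.
#' @return A tagged list understood by [run_jobs()].
#' @export
job_result <- function(value = NULL, children = list(), follow_on = NULL) {
  structure(list(value = value, children = children, follow_on = follow_on),
            class = "metalign_job_result")
}

#' Run a job hierarchy
#'
#' Executes the dynamic hierarchy respecting child / follow-on ordering.
#' `mode = "serial"` runs everything in order in the current process;
#' `mode = "parallel"` runs same-level children concurrently on forked
#' workers (results are collected in child order, so outputs are identical
#' across modes and worker counts for deterministic actions). On failure the
#' error names the failed job and its ancestry and pending descendants are
#' not started.
#'
#' @param root A [job].
#' @param mode `"serial"` or `"parallel"`.
#' @param workers Worker count for parallel mode (>= 1).
#' @return List with `value` (the hierarchy's final value: the outermost
#'   follow-on chain's value) and `report`, a data frame of completed jobs
#'   in completion order (`id`, `parent`, `n_children`).
#' @export
run_jobs <- function(root, mode = c("serial", "parallel"), workers = 1L) {
  mode <- match.arg(mode)
  if (workers < 1L) stop_input("workers must be >= 1")
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  value <- exec_job(root, mode, workers, ancestry = character(0), log_env)
  report <- do.call(rbind, c(log_env$rows, list(make.row.names = FALSE)))
  if (is.null(report)) {
    report <- data.frame(id = character(0), parent = character(0),
                         n_children = integer(0), stringsAsFactors = FALSE)
  }
  list(value = value, report = report)
}

exec_job <- function(j, mode, workers, ancestry, log_env) {
  if (j$id %in% ancestry) {
    stop_internal("job scheduling cycle at '", j$id, "' (ancestry: ",
                  paste(ancestry, collapse = " > "), ")")
  }
  tmp <- tempfile(paste0("job_", gsub("[^A-Za-z0-9_.-]", "_", j$id), "_"))
  dir.create(tmp, showWarnings = FALSE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  log_at("debug", "start job ", j$id)
  res <- withCallingHandlers(
    tryCatch(do.call(j$action, j$args),
             error = function(e) {
               stop_internal("job '", j$id, "' failed (ancestry: ",
                             paste(c(ancestry, j$id), collapse = " > "),
                             "): ", conditionMessage(e))
             }),
    warning = function(w) w)
  if (!inherits(res, "metalign_job_result")) res <- job_result(value = res)
  kids <- res$children
  child_vals <- list()
  if (length(kids) > 0L) {
    ids <- vapply(kids, `[[`, "", "id")
    if (anyDuplicated(ids)) stop_internal("duplicate child job ids under '", j$id, "'")
    anc <- c(ancestry, j$id)
    if (mode == "parallel" && length(kids) > 1L) {
      child_vals <- parallel::mclapply(kids, function(k) {
        tryCatch(list(ok = TRUE, value = exec_job(k, "serial", 1L, anc, log_env)),
                 error = function(e) list(ok = FALSE, err = conditionMessage(e)))
      }, mc.cores = workers, mc.preschedule = FALSE)
      bad <- !vapply(child_vals, function(x) isTRUE(x$ok), TRUE)
      if (any(bad)) {
        first <- child_vals[[which(bad)[1L]]]
        stop_internal(first$err)
      }
      child_vals <- lapply(child_vals, `[[`, "value")
    } else {
      child_vals <- lapply(kids, exec_job, mode = mode, workers = workers,
                           ancestry = anc, log_env = log_env)
    }
    names(child_vals) <- ids
  }
  log_env$rows[[length(log_env$rows) + 1L]] <-
    data.frame(id = j$id,
               parent = if (length(ancestry) > 0L) tail(ancestry, 1L) else NA_character_,
               n_children = length(kids), stringsAsFactors = FALSE)
  final <- res$value
  if (!is.null(res$follow_on)) {
    fo <- res$follow_on(res$value, child_vals)
    if (!is.null(fo)) {
      if (!inherits(fo, "metalign_job")) {
        stop_internal("follow_on of '", j$id, "' must return a job or NULL")
      }
      final <- exec_job(fo, mode, workers, c(ancestry, j$id), log_env)
    }
  } else if (length(child_vals) > 0L) {
    final <- child_vals
  }
  log_at("debug", "done job ", j$id)
  final
}
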