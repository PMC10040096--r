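#' @title Run orchestration
#' @description
#' The submit/status/delete trio drives a run end to end: `submit` splits
#' the queries, computes the search plan and enqueues one job per batch;
#' `status` reads back per-state job counts from the persisted manifest;
#' `delete` releases everything except results already written. Execution
#' itself happens through [run_local()] (a local process executor honouring
#' the retry/fail-fast state machine) or [simulate_cluster()] (a
#' discrete-event model of the autoscaled cluster).
#' @name orchestrator
NULL

new_run_id <- function() {
  sprintf("run-%s-%04x", format(Sys.time(), "%Y%m%d%H%M%S"),
          sample.int(65535L, 1L))
}

manifest_path <- function(state_dir) file.path(state_dir, "run.json")

jobs_to_list <- function(jobs) {
  lapply(jobs, function(j) {
    list(job_id = j$job_id, batch_index = j$batch_index, state = j$state,
         attempts = j$attempts, last_failure = j$last_failure,
         result_locator = if (is.na(j$result_locator)) NULL else j$result_locator,
         batch_len = if (is.na(j$batch_len)) NULL else j$batch_len)
  })
}

jobs_from_list <- function(lst) {
  lapply(lst, function(x) {
    j <- make_job(x$job_id, x$batch_index,
                  if (is.null(x$batch_len)) NA_real_ else x$batch_len)
    j$state <- x$state
    j$attempts <- as.integer(x$attempts)
    j$last_failure <- x$last_failure
    j$result_locator <- if (is.null(x$result_locator)) NA_character_
                        else x$result_locator
    j
  })
}

write_manifest <- function(manifest, state_dir) {
  write_json_atomic(manifest, manifest_path(state_dir))
}

read_manifest <- function(state_dir) {
  path <- manifest_path(state_dir)
  if (!file.exists(path)) {
    stop("no run manifest at ", path, " (unknown run?)", call. = FALSE)
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Submit a run
#'
#' Reads and splits the query set, computes the search plan, persists the
#' query batches and a JSON run manifest under the run's state directory,
#' and enqueues one PENDING job per batch. No search is executed yet; see
#' [execute_run()].
#'
#' @param config A `run_config` (see [parse_config()]). `queries` and `db`
#'   are resolved through `store`; `db` must name a database metadata JSON
#'   document.
#' @param store An [object_store()] backing bucket-style locators and
#'   holding run state under `<root>/runs/<run_id>`.
#' @param catalog Instance catalog (defaults to the bundled fixture).
#' @param margin Memory safety margin for the planner.
#' @param run_id Optional explicit run identifier; must not collide with an
#'   active run.
#' @return A `run_handle`: `run_id`, `config`, `state_dir`.
#' @export
submit <- function(config, store, catalog = load_catalog(catalog_fixture_path()),
                   margin = 1.1, run_id = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(store, "object_store"))
  if (is.null(run_id)) run_id <- new_run_id()
  state_dir <- file.path(store$root, "runs", run_id)
  if (file.exists(manifest_path(state_dir))) {
    existing <- read_manifest(state_dir)
    if (!isTRUE(existing$deleted)) {
      stop("run id '", run_id, "' already has an active manifest", call. = FALSE)
    }
  }

  records <- read_sequences(config$queries, store)
  if (nrow(records) == 0) {
    stop("query source '", config$queries,
         "' contains no sequences; nothing submitted", call. = FALSE)
  }
  meta <- load_metadata(config$db, store)
  plan <- make_plan(config, meta, catalog, margin = margin,
                    query_total_length = sum(records$length))
  split <- split_queries(records, plan$batch_len)
  batch_paths <- write_batches(split, file.path(state_dir, "batches"))
  jobs <- lapply(seq_along(split$batches), function(i) {
    make_job(sprintf("%s-job-%03d", run_id, i - 1L), i - 1L,
             sum(split$batches[[i]]$length))
  })
  results_dir <- store_resolve(store, config$results, create = TRUE)
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    run_id = run_id,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    deleted = FALSE,
    config = unclass(config),
    plan = list(
      instance = plan$instance$name, vcpus = plan$instance$vcpus,
      ram_gb = plan$instance$ram_gb, hourly_price = plan$instance$hourly_price,
      spot_discount = plan$instance$spot_discount,
      processes = plan$thread_plan$processes,
      threads_per_process = plan$thread_plan$threads_per_process,
      mode = plan$thread_plan$mode,
      batch_len = plan$batch_len, max_nodes = plan$max_nodes,
      preemptible = plan$preemptible,
      memory_bytes_needed = plan$memory$bytes_needed,
      memory_margin = plan$memory$margin),
    totals = split$totals,
    batch_files = as.list(batch_paths),
    results_dir = results_dir,
    workers = list(),
    jobs = jobs_to_list(jobs))
  write_manifest(manifest, state_dir)
  structure(list(run_id = run_id, config = config, state_dir = state_dir),
            class = "run_handle")
}

run_phase <- function(jobs, deleted = FALSE) {
  if (deleted) return("deleted")
  states <- vapply(jobs, function(j) j$state, character(1))
  if (any(states == "FAILED")) "failed"
  else if (length(states) > 0 && all(states == "SUCCEEDED")) "succeeded"
  else if (all(states == "PENDING") &&
           all(vapply(jobs, function(j) j$attempts, integer(1)) == 0L)) "initializing"
  else "running"
}

#' Report run status
#'
#' Read-only: reflects the persisted job states at call time.
#'
#' @param handle A `run_handle` from [submit()].
#' @return A `status_report`: `counts` (named vector: pending, running,
#'   succeeded, failed; summing to the job total) and `phase` (one of
#'   initializing, running, succeeded, failed, deleted).
#' @export
status <- function(handle) {
  stopifnot(inherits(handle, "run_handle"))
  manifest <- read_manifest(handle$state_dir)
  jobs <- jobs_from_list(manifest$jobs)
  states <- vapply(jobs, function(j) j$state, character(1))
  counts <- c(pending = sum(states == "PENDING"),
              running = sum(states == "RUNNING"),
              succeeded = sum(states == "SUCCEEDED"),
              failed = sum(states == "FAILED"))
  structure(list(counts = counts,
                 phase = run_phase(jobs, isTRUE(manifest$deleted)),
                 run_id = manifest$run_id),
            class = "status_report")
}

#' @export
print.status_report <- function(x, ...) {
  cat(sprintf("<status_report> %s: phase=%s | pending=%d running=%d succeeded=%d failed=%d\n",
              x$run_id, x$phase, x$counts[["pending"]], x$counts[["running"]],
              x$counts[["succeeded"]], x$counts[["failed"]]))
  invisible(x)
}

#' Delete a run
#'
#' Releases everything the run allocated — query batches, worker records,
#' state scratch — while leaving result objects already written at the
#' results locator untouched. Idempotent: deleting a deleted (or
#' auto-shut-down) run is a no-op success.
#'
#' @param handle A `run_handle`.
#' @return A `teardown_report`: `run_id`, `noop`, `results_retained` (count
#'   of result objects still present).
#' @export
delete <- function(handle) {
  stopifnot(inherits(handle, "run_handle"))
  manifest <- read_manifest(handle$state_dir)
  results_retained <- length(list.files(manifest$results_dir,
                                        pattern = "\\.out\\.gz$"))
  if (isTRUE(manifest$deleted)) {
    return(structure(list(run_id = manifest$run_id, noop = TRUE,
                          results_retained = results_retained),
                     class = "teardown_report"))
  }
  unlink(file.path(handle$state_dir, "batches"), recursive = TRUE)
  manifest$deleted <- TRUE
  manifest$workers <- list()
  manifest$batch_files <- list()
  write_manifest(manifest, handle$state_dir)
  structure(list(run_id = manifest$run_id, noop = FALSE,
                 results_retained = results_retained),
            class = "teardown_report")
}

#' @export
print.teardown_report <- function(x, ...) {
  cat(sprintf("<teardown_report> %s: %s; %d result object(s) retained\n",
              x$run_id, if (x$noop) "no-op (already deleted)" else "deleted",
              x$results_retained))
  invisible(x)
}

result_file_name <- function(batch_index) {
  sprintf("batch_%03d.out.gz", batch_index)
}

invoke_executor <- function(executor, batch_file, batch_index, attempt,
                            db, threads, options) {
  if (is.function(executor)) {
    return(executor(batch_file, batch_index, attempt, db = db,
                    threads = threads, options = options))
  }
  # command template: character vector with {query} {db} {threads} {options}
  fill <- function(x) {
    x <- gsub("{query}", batch_file, x, fixed = TRUE)
    x <- gsub("{db}", db %||% "", x, fixed = TRUE)
    x <- gsub("{threads}", as.character(threads %||% 1L), x, fixed = TRUE)
    gsub("{options}", options %||% "", x, fixed = TRUE)
  }
  argv <- vapply(executor, fill, character(1))
  out <- suppressWarnings(system2(argv[1], argv[-1], stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  list(status = status, output = as.character(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_result_object <- function(lines, results_dir, batch_index) {
  path <- file.path(results_dir, result_file_name(batch_index))
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  path
}

#' Execute jobs locally
#'
#' Drives every job to a terminal state against a search executor — real
#' BLAST+, the bundled mock, or any command template/function. Jobs are
#' attempted in round-robin sweeps: each pending job gets one execution per
#' sweep, so retries of a flaky batch interleave with first attempts of the
#' others. Non-zero exit codes feed [next_state()] (generic failure,
#' requeued up to the retry budget); the reserved exit code 137 maps to
#' `failure_oom` and fails the job immediately. Fail-fast: once any job is
#' FAILED, no further job is started — results of already-completed jobs
#' remain at the results locator. Successful output is written
#' gzip-compressed, one `batch_<index>.out.gz` object per batch.
#'
#' @param jobs List of `job` records (see [make_job()]).
#' @param plan A `search_plan` (supplies the thread count).
#' @param executor A function `(batch_file, batch_index, attempt, db,
#'   threads, options) -> list(status, output)`, or a command template: a
#'   character vector (command then arguments) with `{query}`, `{db}`,
#'   `{threads}`, `{options}` substitution slots, run via [system2()]. The
#'   opaque BLAST option string passes through untouched.
#' @param batch_paths Batch FASTA paths, indexed by `batch_index + 1`.
#' @param results Results directory or bucket-style locator.
#' @param store Optional [object_store()].
#' @param workers Accepted for interface parity with multi-process
#'   executors; execution is sequential in-process and results do not
#'   depend on it.
#' @param db,options Passed through to the executor.
#' @return A `run_result`: `jobs` (terminal states), `results` (locators of
#'   result objects), `phase` (`"succeeded"` or `"failed"`).
#' @export
run_local <- function(jobs, plan, executor, batch_paths, results,
                      store = NULL, workers = 1L, db = NULL, options = NULL) {
  stopifnot(workers >= 1)
  if (is.character(executor) && !file.exists(executor[1]) &&
      Sys.which(executor[1]) == "") {
    stop("search executable not found: ", executor[1],
         " (nothing was started)", call. = FALSE)
  }
  results_dir <- store_resolve(store, results, create = TRUE)
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  threads <- if (inherits(plan, "search_plan")) plan$thread_plan$threads_per_process
             else 1L
  result_paths <- character(0)

  repeat {
    pending <- which(vapply(jobs, function(j) j$state == "PENDING", logical(1)))
    failed <- any(vapply(jobs, function(j) j$state == "FAILED", logical(1)))
    if (failed || length(pending) == 0) break
    for (i in pending) {
      if (any(vapply(jobs, function(j) j$state == "FAILED", logical(1)))) break
      job <- next_state(jobs[[i]], "start")
      batch_file <- batch_paths[[job$batch_index + 1L]]
      res <- invoke_executor(executor, batch_file, job$batch_index,
                             job$attempts, db, threads, options)
      if (res$status == 0L) {
        path <- write_result_object(res$output, results_dir, job$batch_index)
        job <- next_state(job, "success")
        job$result_locator <- path
        result_paths <- c(result_paths, path)
      } else if (res$status == OOM_EXIT_CODE) {
        job <- next_state(job, "failure_oom")
      } else {
        job <- next_state(job, "failure_generic")
      }
      jobs[[i]] <- job
    }
  }

  structure(list(
    jobs = jobs,
    results = result_paths,
    phase = if (monitor_step(jobs) == "teardown" &&
                any(vapply(jobs, function(j) j$state == "FAILED", logical(1))))
              "failed"
            else if (all(vapply(jobs, function(j) j$state == "SUCCEEDED",
                                logical(1)))) "succeeded"
            else "failed"
  ), class = "run_result")
}

#' Execute a submitted run and update its manifest
#'
#' Convenience wrapper: loads the manifest written by [submit()], runs the
#' pending jobs through [run_local()], and persists the terminal job states
#' back into the manifest.
#'
#' @param handle A `run_handle`.
#' @param executor See [run_local()].
#' @param store The [object_store()] used at submit time.
#' @param workers See [run_local()].
#' @return The updated `status_report`.
#' @export
execute_run <- function(handle, executor, store = NULL, workers = 1L) {
  stopifnot(inherits(handle, "run_handle"))
  manifest <- read_manifest(handle$state_dir)
  if (isTRUE(manifest$deleted)) {
    stop("run '", manifest$run_id, "' has been deleted", call. = FALSE)
  }
  jobs <- jobs_from_list(manifest$jobs)
  plan <- structure(list(
    thread_plan = list(threads_per_process = manifest$plan$threads_per_process)),
    class = "search_plan")
  res <- run_local(jobs, plan, executor,
                   batch_paths = unlist(manifest$batch_files),
                   results = manifest$results_dir, store = store,
                   workers = workers, db = manifest$config$db,
                   options = manifest$config$options)
  manifest$jobs <- jobs_to_list(res$jobs)
  write_manifest(manifest, handle$state_dir)
  status(handle)
}
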