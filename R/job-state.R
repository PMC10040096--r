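#' @title Job state machine
#' @description
#' Every query batch becomes one job. Jobs move PENDING -> RUNNING ->
#' {SUCCEEDED, FAILED}, with cloud-batch retry semantics: a generic failure
#' or a spot-instance preemption requeues the job for up to three retries
#' after the first attempt (at most four executions in total); an
#' out-of-memory failure is flagged FAILED immediately with no retry,
#' because rerunning on the same instance type cannot succeed.
#' @name job-state
NULL

JOB_STATES <- c("PENDING", "RUNNING", "SUCCEEDED", "FAILED")
JOB_EVENTS <- c("start", "success", "failure_generic", "failure_oom",
                "preempted")
MAX_ATTEMPTS <- 4L  # 1 first execution + 3 retries
OOM_EXIT_CODE <- 137L

#' Create a job record
#'
#' @param job_id Identifier (any string).
#' @param batch_index 0-based index of the query batch this job searches.
#' @param batch_len Optional letters in the batch (used by the simulator's
#'   duration model).
#' @return A `job` list: `job_id`, `batch_index`, `state` (`"PENDING"`),
#'   `attempts` (0), `last_failure` (`"none"`), `result_locator` (`NA`),
#'   `batch_len`.
#' @export
make_job <- function(job_id, batch_index, batch_len = NA_real_) {
  structure(list(
    job_id = job_id, batch_index = batch_index, state = "PENDING",
    attempts = 0L, last_failure = "none", result_locator = NA_character_,
    batch_len = batch_len
  ), class = "job")
}

#' Advance a job through one lifecycle event
#'
#' Transition rules: `start` is legal only from PENDING and moves the job to
#' RUNNING, incrementing `attempts`; the remaining events are legal only
#' from RUNNING. `success` -> SUCCEEDED. `failure_oom` -> FAILED (fail-fast,
#' never retried). `failure_generic` and `preempted` requeue the job
#' (PENDING) while `attempts <= 3`, and mark it FAILED once the fourth
#' execution has failed. Preemption consumes a retry slot: the requeue path
#' is the same mechanism as an ordinary failure.
#'
#' @param job A `job`.
#' @param event One of `"start"`, `"success"`, `"failure_generic"`,
#'   `"failure_oom"`, `"preempted"`.
#' @return The updated `job`.
#' @examples
#' j <- make_job("job-0", 0)
#' j <- next_state(j, "start")
#' j <- next_state(j, "preempted")   # requeued
#' j$state; j$attempts
#' @export
next_state <- function(job, event) {
  stopifnot(inherits(job, "job"))
  if (!event %in% JOB_EVENTS) {
    stop("unknown job event '", event, "'", call. = FALSE)
  }
  if (event == "start") {
    if (job$state != "PENDING") {
      stop("illegal transition: 'start' from state ", job$state, call. = FALSE)
    }
    job$state <- "RUNNING"
    job$attempts <- job$attempts + 1L
    return(job)
  }
  if (job$state != "RUNNING") {
    stop("illegal transition: '", event, "' from state ", job$state,
         call. = FALSE)
  }
  if (event == "success") {
    job$state <- "SUCCEEDED"
    job$last_failure <- "none"
  } else if (event == "failure_oom") {
    job$state <- "FAILED"
    job$last_failure <- "oom"
  } else {  # failure_generic or preempted
    job$last_failure <- if (event == "preempted") "preempted" else "generic"
    job$state <- if (job$attempts <= MAX_ATTEMPTS - 1L) "PENDING" else "FAILED"
  }
  job
}

is_terminal <- function(job) job$state %in% c("SUCCEEDED", "FAILED")

#' Auto-shutdown monitor decision
#'
#' The shutdown monitor runs periodically (every `monitor_interval` seconds,
#' 300 by default) and tears down all run resources once every job has
#' succeeded or any job has failed. Repeated teardown decisions are
#' harmless (teardown itself is idempotent).
#'
#' @param jobs List of `job` records.
#' @return `"teardown"` or `"none"`.
#' @export
monitor_step <- function(jobs) {
  states <- vapply(jobs, function(j) j$state, character(1))
  if (length(states) == 0) return("none")
  if (any(states == "FAILED") || all(states == "SUCCEEDED")) "teardown"
  else "none"
}
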