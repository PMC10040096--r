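#' @title Cluster simulator
#' @description
#' A discrete-event model of the autoscaled batch cluster: instances boot
#' (the first alone during a startup period, mirroring cluster
#' configuration and database installation), pull jobs from the queue into
#' per-instance slots (one slot per planned search process), suffer spot
#' preemptions as a Poisson process per busy instance, scale down after a
#' configurable idle lag, and are torn down by the periodic shutdown
#' monitor once all jobs have succeeded or any has failed. Per-instance
#' uptime feeds a billing meter, so the cost consequences of scheduling
#' choices (e.g. paying for the scale-down lag on wide clusters) are
#' measurable. Time is tracked in seconds internally and reported in hours.
#' @name cluster-simulator
NULL

#' Simulation parameters
#'
#' @param startup_delay_s Seconds before the first instance is productive
#'   (cluster configuration + database installation; production-scale runs
#'   see up to ~22 min). Default 0.
#' @param job_duration Either a single number (seconds per job) or a
#'   function mapping batch length to runtime seconds.
#' @param preemption_rate Expected preemptions per busy instance-hour; 0
#'   for on-demand capacity.
#' @param monitor_interval_s Shutdown-monitor period in seconds (default
#'   300, i.e. the 5-minute check).
#' @param scale_down_lag_s Seconds between an instance going idle and its
#'   shutdown (the managed service's detection lag). Default 0.
#' @param restart_delay_s Seconds to replace a preempted instance.
#' @param seed Integer RNG seed; the simulation is deterministic for a
#'   fixed seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(startup_delay_s = 0, job_duration = 3600,
                       preemption_rate = 0, monitor_interval_s = 300,
                       scale_down_lag_s = 0, restart_delay_s = 120,
                       seed = 1L) {
  stopifnot(startup_delay_s >= 0, preemption_rate >= 0,
            monitor_interval_s > 0, scale_down_lag_s >= 0,
            restart_delay_s >= 0)
  structure(list(startup_delay_s = startup_delay_s,
                 job_duration = job_duration,
                 preemption_rate = preemption_rate,
                 monitor_interval_s = monitor_interval_s,
                 scale_down_lag_s = scale_down_lag_s,
                 restart_delay_s = restart_delay_s,
                 seed = seed), class = "sim_params")
}

job_duration_s <- function(params, batch_len) {
  if (is.function(params$job_duration)) params$job_duration(batch_len)
  else params$job_duration
}

#' Simulate a run on an autoscaled cluster
#'
#' Event-driven execution of `jobs` under `plan` and `params`: at most
#' `plan$max_nodes` instances, each offering `plan$thread_plan$processes`
#' concurrent job slots; instance 1 becomes productive after
#' `startup_delay_s`, further instances join once it is productive and only
#' while the outstanding queue warrants them; busy instances are preempted
#' at `preemption_rate` per instance-hour (every job on a preempted
#' instance requeues through [next_state()], consuming a retry slot, and a
#' replacement boots after `restart_delay_s`); instances idle for
#' `scale_down_lag_s` shut down; once all jobs are terminal (or the retry
#' budget turns a job FAILED) the monitor tears the cluster down at its
#' next tick. Billed hours are the summed uptime of every instance.
#'
#' @param jobs List of `job` records ([make_job()]), or an integer for that
#'   many identical jobs.
#' @param plan A `search_plan`, or a list with `max_nodes`, `preemptible`
#'   and `thread_plan$processes`.
#' @param params A [sim_params()].
#' @return A `sim_result`: `makespan_h` (finish of the last terminal job),
#'   `teardown_h`, `billed_hours` (total and per pricing class),
#'   `instances` (per-instance boot/shutdown/uptime data frame), `jobs`
#'   (terminal records), `timeline` (event data frame), `phase`,
#'   `max_concurrent_instances`.
#' @examples
#' plan <- list(max_nodes = 2, preemptible = FALSE,
#'              thread_plan = list(processes = 1))
#' sim <- simulate_cluster(8, plan, sim_params(job_duration = 3600))
#' sim$makespan_h  # 4: eight 1-hour jobs over two single-slot instances
#' @export
simulate_cluster <- function(jobs, plan, params = sim_params()) {
  if (is.numeric(jobs) && length(jobs) == 1L) {
    jobs <- lapply(seq_len(jobs), function(i) {
      make_job(sprintf("sim-job-%03d", i - 1L), i - 1L)
    })
  }
  stopifnot(inherits(params, "sim_params"))
  if (length(jobs) == 0) stop("no jobs to simulate", call. = FALSE)
  max_nodes <- plan$max_nodes
  slots <- plan$thread_plan$processes
  preemptible <- isTRUE(plan$preemptible)
  rate_s <- params$preemption_rate / 3600

  n <- length(jobs)
  with_local_seed(params$seed, {
    # instance table (grown as needed)
    inst <- data.frame(id = integer(), boot = numeric(), ready = numeric(),
                       down = numeric(), preempt_at = numeric(),
                       idle_since = numeric(), alive = logical())
    running <- list()  # per instance id: list of list(job = idx, end = t)
    timeline <- list()
    ev <- function(t, event, instance = NA, job = NA) {
      timeline[[length(timeline) + 1L]] <<- data.frame(
        time_s = t, event = event, instance = instance, job = job)
    }
    boot_instance <- function(t, ready_at) {
      id <- nrow(inst) + 1L
      inst[id, ] <<- list(id, t, ready_at, NA_real_, Inf, NA_real_, TRUE)
      running[[id]] <<- list()
      ev(t, "instance_boot", instance = id)
      id
    }
    shutdown_instance <- function(id, t) {
      inst$down[id] <<- t
      inst$alive[id] <<- FALSE
      inst$idle_since[id] <<- NA_real_
      inst$preempt_at[id] <<- Inf
      ev(t, "instance_down", instance = id)
    }
    draw_preemption <- function(id, t) {
      inst$preempt_at[id] <<- if (preemptible && rate_s > 0) {
        t + stats::rexp(1, rate_s)
      } else {
        Inf
      }
    }

    t <- 0
    boot_instance(0, params$startup_delay_s)
    max_concurrent <- 1L
    last_terminal_t <- NA_real_

    job_state <- function(i) jobs[[i]]$state
    outstanding <- function() sum(vapply(seq_len(n), function(i) {
      job_state(i) %in% c("PENDING", "RUNNING")
    }, logical(1)))

    repeat {
      # --- scale up: once the first instance is productive, grow toward the
      # number of instances the outstanding queue can use, capped by the
      # user's node limit
      first_ready <- min(inst$ready[1], Inf)
      if (t >= first_ready) {
        desired <- min(max_nodes, ceiling(outstanding() / slots))
        while (sum(inst$alive) < desired) boot_instance(t, t)
      }
      max_concurrent <- max(max_concurrent, sum(inst$alive))

      # --- assign pending jobs to free slots on productive instances
      pending <- which(vapply(seq_len(n), function(i) job_state(i) == "PENDING",
                              logical(1)))
      for (id in which(inst$alive & inst$ready <= t)) {
        free <- slots - length(running[[id]])
        while (free > 0 && length(pending) > 0) {
          i <- pending[1]; pending <- pending[-1]
          jobs[[i]] <- next_state(jobs[[i]], "start")
          dur <- job_duration_s(params, jobs[[i]]$batch_len)
          was_idle <- length(running[[id]]) == 0
          running[[id]][[length(running[[id]]) + 1L]] <-
            list(job = i, end = t + dur)
          if (was_idle) draw_preemption(id, t)
          inst$idle_since[id] <- NA_real_
          ev(t, "job_start", instance = id, job = jobs[[i]]$job_id)
          free <- free - 1
        }
      }

      # --- mark newly idle instances (no running slot, nothing to pull)
      if (length(pending) == 0) {
        for (id in which(inst$alive & inst$ready <= t)) {
          if (length(running[[id]]) == 0 && is.na(inst$idle_since[id])) {
            inst$idle_since[id] <- t
            inst$preempt_at[id] <- Inf
          }
        }
      }

      # --- scale down instances whose idle lag has elapsed; the shutdown is
      # stamped at idle_since + lag even when observed later
      for (id in which(inst$alive)) {
        if (!is.na(inst$idle_since[id]) && length(running[[id]]) == 0 &&
            inst$idle_since[id] + params$scale_down_lag_s <= t) {
          shutdown_instance(id, inst$idle_since[id] + params$scale_down_lag_s)
        }
      }

      # --- termination check
      terminal <- all(vapply(seq_len(n), function(i) {
        job_state(i) %in% c("SUCCEEDED", "FAILED")
      }, logical(1)))
      if (terminal || monitor_step(jobs) == "teardown") {
        makespan <- last_terminal_t
        # the monitor's check at a tick observes state strictly before the
        # tick, so detection happens at the first tick after completion
        teardown <- (floor(makespan / params$monitor_interval_s) + 1) *
          params$monitor_interval_s
        for (id in which(inst$alive)) {
          down_at <- if (!is.na(inst$idle_since[id])) {
            min(inst$idle_since[id] + params$scale_down_lag_s, teardown)
          } else {
            teardown  # cancelled with the cluster (fail-fast teardown)
          }
          shutdown_instance(id, max(down_at, t))
        }
        break
      }

      # --- next event time
      ends <- unlist(lapply(which(inst$alive), function(id) {
        vapply(running[[id]], function(r) r$end, numeric(1))
      }))
      idle_downs <- inst$idle_since[inst$alive] + params$scale_down_lag_s
      candidates <- c(ends, inst$preempt_at[inst$alive],
                      inst$ready[inst$alive & inst$ready > t],
                      idle_downs[!is.na(idle_downs)])
      candidates <- candidates[is.finite(candidates) & candidates > t]
      if (length(candidates) == 0) {
        stop("simulator deadlock: no future events with jobs outstanding",
             call. = FALSE)  # cannot happen with a live queue
      }
      t <- min(candidates)

      # --- process events at t
      for (id in which(inst$alive)) {
        if (inst$preempt_at[id] <= t) {
          # spot reclaim: requeue every running job, replace the instance
          for (r in running[[id]]) {
            jobs[[r$job]] <- next_state(jobs[[r$job]], "preempted")
            if (jobs[[r$job]]$state == "FAILED") last_terminal_t <- t
            ev(t, "job_preempted", instance = id, job = jobs[[r$job]]$job_id)
          }
          running[[id]] <- list()
          shutdown_instance(id, t)
          boot_instance(t, t + params$restart_delay_s)
          next
        }
        done <- vapply(running[[id]], function(r) r$end <= t, logical(1))
        for (r in running[[id]][done]) {
          jobs[[r$job]] <- next_state(jobs[[r$job]], "success")
          last_terminal_t <- t
          ev(t, "job_success", instance = id, job = jobs[[r$job]]$job_id)
        }
        running[[id]] <- running[[id]][!done]
      }
    }

    uptime_h <- (inst$down - inst$boot) / 3600
    price_class <- if (preemptible) "preemptible" else "on_demand"
    billed <- sum(uptime_h)
    timeline_df <- do.call(rbind, timeline)
    structure(list(
      makespan_h = last_terminal_t / 3600,
      teardown_h = max(inst$down) / 3600,
      billed_hours = stats::setNames(list(billed), price_class),
      billed_hours_total = billed,
      instances = transform(inst[, c("id", "boot", "down")],
                            uptime_h = uptime_h),
      jobs = jobs,
      timeline = timeline_df,
      phase = if (any(vapply(jobs, function(j) j$state == "FAILED",
                             logical(1)))) "failed" else "succeeded",
      max_concurrent_instances = max_concurrent,
      params = params
    ), class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: makespan %.2f h, teardown %.2f h, billed %.2f instance-hours (%s), peak %d instance(s)\n",
              x$phase, x$makespan_h, x$teardown_h, x$billed_hours_total,
              names(x$billed_hours)[1], x$max_concurrent_instances))
  invisible(x)
}

#' Write simulator outputs
#'
#' Emits the event timeline as JSON and per-instance uptimes as CSV.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
sim_write_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  timeline_path <- file.path(dir, "timeline.json")
  jsonlite::write_json(sim$timeline, timeline_path, digits = NA,
                       na = "null", pretty = TRUE)
  uptime_path <- file.path(dir, "instance_uptime.csv")
  utils::write.csv(sim$instances, uptime_path, row.names = FALSE)
  invisible(c(timeline = timeline_path, uptimes = uptime_path))
}
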