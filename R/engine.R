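#' Job runs and stage runs
#'
#' A `JobRun` is the runtime record of one workflow submission: overall
#' status (`QUEUED`, `RUNNING`, `HELD`, `COMPLETED`, `FAILED`,
#' `CANCELLED`), one stage run per workflow stage, and the job's working
#' directory.  Stage runs move `WAITING` -> `RUNNING` -> one terminal
#' state of `COMPLETED` (exit 0), `FAILED` (nonzero exit or backend
#' abort), `SKIPPED` (an incoming conditional edge became permanently
#' unsatisfiable) or `CANCELLED`; `READY` is the transient condition
#' computed by [ready_stages()].  All stages of a run share the working
#' directory, so downstream stages see their predecessors' outputs on the
#' filesystem.
#'
#' @docType class
#' @export
JobRun <- R6::R6Class("JobRun",
  public = list(
    #' @field job_id unique id.
    job_id = NULL,
    #' @field workflow,version workflow name and published version string.
    workflow = NULL,
    #' @field version published version string.
    version = NULL,
    #' @field user submitting user.
    user = NULL,
    #' @field status job state.
    status = "QUEUED",
    #' @field stage_runs named list of stage-run records.
    stage_runs = list(),
    #' @field working_dir per-job directory.
    working_dir = NULL,
    #' @field created_at,finished_at POSIXct timestamps.
    created_at = NULL,
    #' @field finished_at completion timestamp.
    finished_at = NULL,
    #' @field held engine-level hold flag.
    held = FALSE,
    #' @field failed a failure rule has fired.
    failed = FALSE,
    #' @field stages_by_id frozen stage content keyed by stage id.
    stages_by_id = NULL,
    #' @field deps list of dependency edges (frozen content).
    deps = NULL,
    #' @field tools frozen tool versions keyed by `tool@version`.
    tools = NULL,
    #' @field eligible checkpoint-eligible stage ids.
    eligible = NULL,
    #' @field max_workers concurrent stage limit for this run.
    max_workers = 2L,
    #' @field jitter optional function slept before each launch (seconds).
    jitter = NULL,
    #' @field resumed_from job id this run was resumed from, if any.
    resumed_from = NULL
  )
)

new_stage_run <- function(stage_id, resolved_parameters = list()) {
  list(stage_id = stage_id, state = "WAITING", exit_status = NULL,
       stdout = NULL, stderr = NULL, resolved_parameters = resolved_parameters,
       backend_job_id = NULL, snapshot_ref = NULL, post_snapshot_ref = NULL,
       started_at = NULL, finished_at = NULL, carried = FALSE)
}

STAGE_TERMINAL <- c("COMPLETED", "FAILED", "SKIPPED", "CANCELLED")
JOB_TERMINAL <- c("COMPLETED", "FAILED", "CANCELLED")

#' Does a conditional dependency fire for a finished parent stage?
#'
#' `on_success` fires on exit status 0, `on_fail` on any nonzero exit or
#' a backend-reported abort (a failed stage with no exit code), and
#' `on_exit_code` on the exact code.  An `on_exit_code` edge with code 0
#' is synonymous with `on_success`.  Cancelled parents trigger nothing.
#'
#' @param dependency a [stage_dependency()] (or frozen edge content).
#' @param parent_stage_run the parent's stage-run record; must be in a
#'   finished state (`COMPLETED` or `FAILED`).
#' @return logical.
#' @export
evaluate_condition <- function(dependency, parent_stage_run) {
  st <- parent_stage_run$state
  if (!st %in% c("COMPLETED", "FAILED")) {
    abort(sprintf("parent stage '%s' has not finished (state %s)",
                  parent_stage_run$stage_id, st))
  }
  exit <- parent_stage_run$exit_status
  switch(dependency$condition,
    on_success = !is.null(exit) && exit == 0L,
    on_fail = is.null(exit) || exit != 0L,
    on_exit_code = !is.null(exit) && exit == as.integer(dependency$code),
    abort(sprintf("unknown condition '%s'", dependency$condition)))
}

#' Stages ready to launch
#'
#' A waiting stage is ready iff every one of its incoming edges'
#' conditions evaluates true (AND across incoming edges); stages with no
#' incoming edges are ready at the start.  The result is deterministic
#' given the stage states and sorted by stage id.
#'
#' @param job_run a [JobRun].
#' @return character vector of ready stage ids.
#' @export
ready_stages <- function(job_run) {
  ready <- character()
  for (sid in names(job_run$stages_by_id)) {
    sr <- job_run$stage_runs[[sid]]
    if (sr$state != "WAITING") next
    incoming <- Filter(function(d) identical(d$child, sid), job_run$deps)
    ok <- TRUE
    for (d in incoming) {
      p <- job_run$stage_runs[[d$parent]]
      if (!p$state %in% c("COMPLETED", "FAILED") || !evaluate_condition(d, p)) {
        ok <- FALSE
        break
      }
    }
    if (ok) ready <- c(ready, sid)
  }
  sort(ready)
}

#' Apply skip and failure rules after a stage finishes
#'
#' Children whose incoming edges can no longer all be satisfied are
#' marked `SKIPPED`, transitively.  The job is marked failed when (a) the
#' finished stage has outgoing edges and none of their conditions
#' matched, or (b) the stage failed and no `on_fail` / matching
#' `on_exit_code` edge consumes the failure — which for a terminal stage
#' means any unconsumed nonzero exit fails the job.
#'
#' @param job_run a [JobRun]; mutated in place.
#' @param finished_stage stage id that just reached a finished state.
#' @return the job run, invisibly.
#' @export
propagate_completion <- function(job_run, finished_stage) {
  sr <- job_run$stage_runs[[finished_stage]]
  out <- Filter(function(d) identical(d$parent, finished_stage), job_run$deps)
  if (length(out)) {
    matched <- vapply(out, evaluate_condition, logical(1),
                      parent_stage_run = sr)
    if (!any(matched)) job_run$failed <- TRUE
  }
  if (sr$state == "FAILED") {
    consumers <- Filter(function(d) {
      d$condition == "on_fail" ||
        (d$condition == "on_exit_code" && !is.null(sr$exit_status) &&
           as.integer(d$code) == sr$exit_status)
    }, out)
    if (length(consumers) == 0) job_run$failed <- TRUE
  }
  mark_unreachable_skipped(job_run)
  invisible(job_run)
}

# a WAITING stage whose incoming edges include one that is permanently
# unsatisfiable (finished parent, condition false; or skipped/cancelled
# parent) can never run: SKIP it, transitively
mark_unreachable_skipped <- function(job_run) {
  repeat {
    changed <- FALSE
    for (sid in names(job_run$stages_by_id)) {
      sr <- job_run$stage_runs[[sid]]
      if (sr$state != "WAITING") next
      incoming <- Filter(function(d) identical(d$child, sid), job_run$deps)
      dead <- vapply(incoming, function(d) {
        p <- job_run$stage_runs[[d$parent]]
        if (p$state %in% c("SKIPPED", "CANCELLED")) return(TRUE)
        if (p$state %in% c("COMPLETED", "FAILED")) return(!evaluate_condition(d, p))
        FALSE
      }, logical(1))
      if (any(dead)) {
        job_run$stage_runs[[sid]]$state <- "SKIPPED"
        job_run$stage_runs[[sid]]$finished_at <- Sys.time()
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  invisible(job_run)
}

#' The job manager: submission, scheduling, resume, batch, control
#'
#' The central runtime object.  It owns a registry (where the workflow
#' versions live), a backend (where stage processes run), a configuration
#' and a [history_store()]; jobs submitted through it get a working
#' directory under `<workdir_root>/<user>/<job_id>/`, sidecar files
#' `stage_<id>.out|.err|.exit` per stage, and snapshots under
#' `.snapshots/`.
#'
#' @param registry a [tool_registry()].
#' @param backend a [ResourceBackend]; default [local_backend()].
#' @param config a [stageflow_config()].
#' @param history a [history_store()]; default a fresh store under the
#'   working-directory root.
#' @return a `JobManager` R6 object.
#' @examples
#' \dontrun{
#' jm <- job_manager(reg)
#' job <- jm$submit("my-workflow", "1.0.0", user = "ann",
#'                  inputs = list(reads = "sample.fq"))
#' tidy(job)
#' }
#' @export
job_manager <- function(registry, backend = local_backend(),
                        config = stageflow_config(), history = NULL) {
  JobManager$new(registry, backend, config, history)
}

#' @rdname job_manager
#' @export
JobManager <- R6::R6Class("JobManager",
  public = list(
    #' @field registry the tool/workflow registry.
    registry = NULL,
    #' @field backend the resource-manager backend.
    backend = NULL,
    #' @field config runtime configuration.
    config = NULL,
    #' @field history persistent job history store.
    history = NULL,

    #' @description Create a manager.
    #' @param registry,backend,config,history see [job_manager()].
    initialize = function(registry, backend = local_backend(),
                          config = stageflow_config(), history = NULL) {
      self$registry <- registry
      self$backend <- backend
      self$config <- config
      self$history <- history %||%
        history_store(file.path(config$workdir_root, ".history"))
      private$jobs <- new.env(parent = emptyenv())
    },

    #' @description Submit a workflow version as a new job.
    #' @param workflow workflow name.
    #' @param version published version string.
    #' @param user submitting user; needs the RUN right.
    #' @param inputs named list of user parameter values; keys are bare
    #'   parameter keys or `"stage_id.key"` to disambiguate.
    #' @param profile an [input_profile()], or the name of a profile saved
    #'   in the registry.
    #' @param run drive the job to completion before returning.
    #' @param max_workers concurrent stage limit (default from config).
    #' @param jitter optional function returning seconds to sleep before
    #'   each stage launch (scheduling perturbation for tests).
    submit = function(workflow, version, user = "local", inputs = list(),
                      profile = NULL, run = TRUE, max_workers = NULL,
                      jitter = NULL) {
      if (!self$registry$check_permission(user, "workflow", workflow, "RUN")) {
        abort(sprintf("user '%s' lacks RUN permission on workflow '%s'", user, workflow))
      }
      wfv <- self$registry$workflow_version(workflow, version)
      if (is.character(profile) && length(profile) == 1) {
        profile <- self$registry$profile(profile)
      }
      if (inherits(profile, "input_profile")) {
        expected <- paste0("workflow:", workflow)
        if (!identical(profile$target, expected)) {
          abort(sprintf("profile '%s' targets '%s', not '%s'",
                        profile$name, profile$target, expected))
        }
      }
      job <- private$build_job(wfv, workflow, version, user, inputs, profile,
                               max_workers, jitter)
      assign(job$job_id, job, envir = private$jobs)
      self$history$create_job(job)
      if (run) self$run_job(job)
      job
    },

    #' @description One scheduling tick: poll running stages, record newly
    #'   finished ones, propagate conditions, launch ready stages up to the
    #'   worker limit.
    #' @param job a [JobRun] owned by this manager.
    step = function(job) {
      if (job$status %in% JOB_TERMINAL) return(invisible(job))
      private$poll_running(job)
      if (!job$held && !job$failed) private$launch_ready(job)
      private$finalize_if_done(job)
      invisible(job)
    },

    #' @description Step a job until it reaches a terminal state.
    #' @param job a [JobRun].
    #' @param timeout seconds before giving up.
    run_job = function(job, timeout = 300) {
      deadline <- Sys.time() + timeout
      while (!job$status %in% JOB_TERMINAL) {
        self$step(job)
        if (job$status %in% JOB_TERMINAL) break
        if (job$status == "HELD" && !private$any_running(job)) break
        if (Sys.time() > deadline) abort(sprintf("job '%s' timed out", job$job_id))
        Sys.sleep(0.005)
      }
      invisible(job)
    },

    #' @description Resume a finished job from a checkpoint stage.  The
    #'   new run gets its own working directory, restored from the
    #'   checkpoint's start-of-stage snapshot; stages strictly before the
    #'   checkpoint carry over their recorded results, stages at and after
    #'   it re-execute with the recorded resolved parameters.
    #' @param job_id original job id.
    #' @param stage_id checkpoint stage to resume from.
    #' @param run drive the new job to completion.
    resume = function(job_id, stage_id, run = TRUE) {
      orig <- self$job(job_id)
      if (!orig$status %in% JOB_TERMINAL) {
        abort(sprintf("job '%s' is still active (%s)", job_id, orig$status))
      }
      st <- orig$stages_by_id[[stage_id]]
      if (is.null(st)) abort(sprintf("no stage '%s' in job '%s'", stage_id, job_id))
      sr <- orig$stage_runs[[stage_id]]
      if (!isTRUE(st$is_checkpoint) || is.null(sr$snapshot_ref)) {
        abort(sprintf("stage '%s' is not a checkpoint with a snapshot", stage_id))
      }
      job <- private$clone_for_resume(orig, stage_id, sr$snapshot_ref)
      assign(job$job_id, job, envir = private$jobs)
      self$history$create_job(job)
      for (sid in names(job$stage_runs)) {
        if (job$stage_runs[[sid]]$carried &&
            job$stage_runs[[sid]]$state %in% STAGE_TERMINAL) {
          self$history$record_stage(job$job_id, job$stage_runs[[sid]])
        }
      }
      if (run) self$run_job(job)
      job
    },

    #' @description Submit one job per row of a batch file.
    #' @param workflow,version workflow version to run.
    #' @param batch a file path or literal text: delimited rows of
    #'   parameter values under a header row of parameter keys.
    #' @param user submitting user.
    #' @param run drive each job to completion (jobs are submitted in row
    #'   order, one at a time).
    submit_batch = function(workflow, version, batch, user = "local", run = TRUE) {
      rows <- parse_batch_file(batch, delimiter = self$config$batch_delimiter)
      lapply(seq_len(nrow(rows)), function(i) {
        self$submit(workflow, version, user = user,
                    inputs = as.list(rows[i, , drop = FALSE]), run = run)
      })
    },

    #' @description Cancel, hold, release or delete a job.
    #' @param job_id job id.
    #' @param action one of `"cancel"`, `"hold"`, `"release"`, `"delete"`.
    #' @param user acting user; must own the job or hold ADMIN on the
    #'   workflow.
    #' @param purge with `action = "delete"`, also remove the working
    #'   directory (files are retained by default).
    control = function(job_id, action = c("cancel", "hold", "release", "delete"),
                       user = "local", purge = FALSE) {
      action <- match.arg(action)
      job <- self$job(job_id)
      owner <- identical(user, job$user)
      admin <- tryCatch(
        self$registry$check_permission(user, "workflow", job$workflow, "ADMIN"),
        error = function(e) FALSE)
      if (!owner && !admin) {
        abort(sprintf("user '%s' may not %s job '%s'", user, action, job_id))
      }
      switch(action,
        cancel = private$cancel_job(job),
        hold = {
          if (!job$status %in% c("QUEUED", "RUNNING")) {
            abort(sprintf("cannot hold a %s job", job$status))
          }
          job$held <- TRUE
          job$status <- "HELD"
        },
        release = {
          if (job$status != "HELD") abort("cannot release a job that is not held")
          job$held <- FALSE
          job$status <- if (private$any_running(job)) "RUNNING" else "QUEUED"
          self$run_job(job)
        },
        delete = {
          if (!job$status %in% JOB_TERMINAL) {
            abort(sprintf("cannot delete active job '%s'", job_id))
          }
          self$history$delete_job(job_id)
          if (purge) unlink(job$working_dir, recursive = TRUE)
          rm(list = job_id, envir = private$jobs)
        })
      invisible(self$job_or_null(job_id))
    },

    #' @description Look up a job by id (error if unknown).
    #' @param job_id job id.
    job = function(job_id) {
      j <- self$job_or_null(job_id)
      if (is.null(j)) abort(sprintf("unknown job '%s'", job_id))
      j
    },

    #' @description Look up a job by id, or NULL.
    #' @param job_id job id.
    job_or_null = function(job_id) {
      if (exists(job_id, envir = private$jobs)) get(job_id, envir = private$jobs)
      else NULL
    },

    #' @description Ids of jobs not yet in a terminal state.
    active_jobs = function() {
      ids <- ls(private$jobs)
      ids[vapply(ids, function(i) {
        !get(i, envir = private$jobs)$status %in% JOB_TERMINAL
      }, logical(1))]
    }
  ),

  private = list(
    jobs = NULL,

    build_job = function(wfv, workflow, version, user, inputs, profile,
                         max_workers, jitter) {
      stages <- wfv$content$stages
      names(stages) <- vapply(stages, `[[`, character(1), "stage_id")
      deps <- wfv$content$dependencies
      pvals <- if (inherits(profile, "input_profile")) profile$values else list()

      # inputs and profile values must name a parameter some stage accepts
      # (bare key, or "stage_id.key"); literally bound parameters are fixed
      # by the workflow author and not overridable
      open_keys <- unlist(lapply(names(stages), function(sid) {
        tool <- wfv$tools[[paste(stages[[sid]]$tool, stages[[sid]]$version, sep = "@")]]
        keys <- vapply(tool$content$parameters, `[[`, character(1), "key")
        bound <- names(Filter(function(b) !identical(b, "__user_input__"),
                              stages[[sid]]$bindings))
        open <- setdiff(keys, bound)
        c(open, paste0(sid, ".", open))
      }))
      bad_in <- setdiff(names(inputs), open_keys)
      if (length(bad_in)) {
        abort(sprintf("unknown parameter(s) in inputs: %s",
                      paste(bad_in, collapse = ", ")))
      }
      bad_pv <- setdiff(names(pvals), open_keys)
      if (length(bad_pv)) {
        abort(sprintf("unknown parameter(s) in profile values: %s",
                      paste(bad_pv, collapse = ", ")))
      }

      resolved <- list()
      for (sid in names(stages)) {
        tool <- wfv$tools[[paste(stages[[sid]]$tool, stages[[sid]]$version, sep = "@")]]
        resolved[[sid]] <- resolve_stage_parameters(sid, stages[[sid]],
                                                    tool$content, inputs, pvals)
      }

      job <- JobRun$new()
      job$job_id <- sf_next_id("job")
      job$workflow <- workflow
      job$version <- version
      job$user <- user
      job$created_at <- Sys.time()
      job$stages_by_id <- stages
      job$deps <- deps
      job$tools <- wfv$tools
      job$max_workers <- as.integer(max_workers %||% self$config$max_workers)
      job$jitter <- jitter
      job$eligible <- checkpoint_eligible_stages(workflow_from_canonical(wfv$content))
      job$working_dir <- file.path(self$config$workdir_root, user, job$job_id)
      dir.create(job$working_dir, recursive = TRUE, showWarnings = FALSE)

      for (sid in names(stages)) {
        tool <- wfv$tools[[paste(stages[[sid]]$tool, stages[[sid]]$version, sep = "@")]]
        private$materialize_scripts(job, sid, tool$content)
        resolved[[sid]] <- private$stage_files(job, resolved[[sid]], tool$content)
        job$stage_runs[[sid]] <- new_stage_run(sid, resolved[[sid]])
      }
      job
    },

    materialize_scripts = function(job, sid, tool_content) {
      scripts <- tool_content$scripts
      for (rel in names(scripts)) {
        target <- file.path(job$working_dir, ".tools", sid, rel)
        dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
        con <- file(target, "wb")
        writeBin(charToRaw(scripts[[rel]]), con)
        close(con)
      }
    },

    # copy file parameters pointing at real local files into the job's
    # working directory; the command then sees the staged basename
    stage_files = function(job, vals, tool_content) {
      for (p in tool_content$parameters) {
        if (!identical(p$kind, "file")) next
        v <- vals[[p$key]]
        if (!is.null(v) && is.character(v) && file.exists(v) && !dir.exists(v)) {
          file.copy(v, file.path(job$working_dir, basename(v)), overwrite = TRUE)
          vals[[p$key]] <- basename(v)
        }
      }
      vals
    },

    any_running = function(job) {
      any(vapply(job$stage_runs, function(s) s$state == "RUNNING", logical(1)))
    },

    poll_running = function(job) {
      running <- sort(names(Filter(function(s) s$state == "RUNNING", job$stage_runs)))
      for (sid in running) {
        sr <- job$stage_runs[[sid]]
        st <- self$backend$status(sr$backend_job_id)
        if (st$state == "completed") {
          private$finish_stage(job, sid, st$exit_status)
        } else if (st$state %in% c("unknown", "cancelled")) {
          # backend abort: failed with no exit status
          private$finish_stage(job, sid, NULL)
        }
      }
    },

    finish_stage = function(job, sid, exit_status) {
      sr <- job$stage_runs[[sid]]
      tag <- paste0("stage_", sid)
      sr$stdout <- read_sidecar(job$working_dir, tag, "out", self$config$stream_cap)
      sr$stderr <- read_sidecar(job$working_dir, tag, "err", self$config$stream_cap)
      sr$exit_status <- if (is.null(exit_status)) NULL else as.integer(exit_status)
      sr$state <- if (!is.null(exit_status) && exit_status == 0L) "COMPLETED" else "FAILED"
      sr$finished_at <- Sys.time()
      job$stage_runs[[sid]] <- sr
      if (isTRUE(self$config$snapshot_sequential) && sid %in% job$eligible) {
        job$stage_runs[[sid]]$post_snapshot_ref <-
          take_snapshot(job$working_dir, paste0("after-", sid))
      }
      propagate_completion(job, sid)
      self$history$record_stage(job$job_id, job$stage_runs[[sid]])
    },

    launch_ready = function(job) {
      n_running <- sum(vapply(job$stage_runs, function(s) s$state == "RUNNING",
                              logical(1)))
      slots <- job$max_workers - n_running
      if (slots <= 0) return(invisible())
      for (sid in head(ready_stages(job), slots)) {
        private$launch_stage(job, sid)
      }
    },

    launch_stage = function(job, sid) {
      if (is.function(job$jitter)) Sys.sleep(job$jitter())
      st <- job$stages_by_id[[sid]]
      tool <- job$tools[[paste(st$tool, st$version, sep = "@")]]
      sr <- job$stage_runs[[sid]]
      if (isTRUE(st$is_checkpoint)) {
        sr$snapshot_ref <- take_snapshot(job$working_dir, paste0("checkpoint-", sid))
      }
      vals <- c(sr$resolved_parameters,
                list(SCRIPTS = file.path(".tools", sid)))
      command <- resolve_command(tool$content$command_template, vals)
      sr$state <- "RUNNING"
      sr$started_at <- Sys.time()
      sr$backend_job_id <- self$backend$submit(command, job$working_dir,
                                               tag = paste0("stage_", sid))
      job$stage_runs[[sid]] <- sr
      if (job$status == "QUEUED") job$status <- "RUNNING"
    },

    finalize_if_done = function(job) {
      states <- vapply(job$stage_runs, `[[`, character(1), "state")
      if (any(states == "RUNNING")) return(invisible())
      if (job$failed) {
        for (sid in names(states)[states == "WAITING"]) {
          job$stage_runs[[sid]]$state <- "SKIPPED"
          job$stage_runs[[sid]]$finished_at <- Sys.time()
          self$history$record_stage(job$job_id, job$stage_runs[[sid]])
        }
        private$finish_job(job, "FAILED")
      } else if (all(states %in% STAGE_TERMINAL)) {
        private$finish_job(job, "COMPLETED")
      } else if (!job$held && length(ready_stages(job)) == 0 &&
                 !any(states == "RUNNING")) {
        # nothing running, nothing ready, non-terminal stages left: the
        # remaining waits are unsatisfiable
        mark_unreachable_skipped(job)
        states <- vapply(job$stage_runs, `[[`, character(1), "state")
        if (all(states %in% STAGE_TERMINAL)) {
          private$finish_job(job, if (job$failed) "FAILED" else "COMPLETED")
        }
      }
    },

    finish_job = function(job, status) {
      job$status <- status
      job$finished_at <- Sys.time()
      self$history$finalize_job(job)
    },

    cancel_job = function(job) {
      if (job$status %in% JOB_TERMINAL) {
        abort(sprintf("cannot cancel a %s job", job$status))
      }
      for (sid in names(job$stage_runs)) {
        sr <- job$stage_runs[[sid]]
        if (sr$state == "RUNNING") {
          try(self$backend$cancel(sr$backend_job_id), silent = TRUE)
          job$stage_runs[[sid]]$state <- "CANCELLED"
          job$stage_runs[[sid]]$finished_at <- Sys.time()
          self$history$record_stage(job$job_id, job$stage_runs[[sid]])
        } else if (sr$state == "WAITING") {
          job$stage_runs[[sid]]$state <- "CANCELLED"
          job$stage_runs[[sid]]$finished_at <- Sys.time()
          self$history$record_stage(job$job_id, job$stage_runs[[sid]])
        }
      }
      private$finish_job(job, "CANCELLED")
    },

    clone_for_resume = function(orig, stage_id, snapshot_ref) {
      job <- JobRun$new()
      job$job_id <- sf_next_id("job")
      job$workflow <- orig$workflow
      job$version <- orig$version
      job$user <- orig$user
      job$created_at <- Sys.time()
      job$stages_by_id <- orig$stages_by_id
      job$deps <- orig$deps
      job$tools <- orig$tools
      job$max_workers <- orig$max_workers
      job$eligible <- orig$eligible
      job$resumed_from <- orig$job_id
      job$working_dir <- file.path(self$config$workdir_root, job$user, job$job_id)
      dir.create(job$working_dir, recursive = TRUE, showWarnings = FALSE)

      # restore the checkpoint's start-of-stage snapshot into the new dir
      snap_dir <- file.path(orig$working_dir, ".snapshots", snapshot_ref)
      if (!dir.exists(snap_dir)) abort(sprintf("snapshot '%s' missing on disk", snapshot_ref))
      for (rel in list.files(snap_dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)) {
        target <- file.path(job$working_dir, rel)
        dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
        file.copy(file.path(snap_dir, rel), target)
      }

      # ancestors of the checkpoint carry their recorded results; the
      # checkpoint and everything after it re-execute
      reach <- reachability(names(orig$stages_by_id), orig$deps)
      before <- names(orig$stages_by_id)[reach[, stage_id] &
                                           names(orig$stages_by_id) != stage_id]
      for (sid in names(orig$stage_runs)) {
        sr <- orig$stage_runs[[sid]]
        if (sid %in% before) {
          sr$carried <- TRUE
          job$stage_runs[[sid]] <- sr
        } else {
          job$stage_runs[[sid]] <- new_stage_run(sid, sr$resolved_parameters)
        }
      }
      job
    }
  )
)

# boolean reachability matrix (i reaches j, reflexive) over the frozen edges
reachability <- function(ids, deps) {
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(m) <- TRUE
  for (d in deps) m[d$parent, d$child] <- TRUE
  for (k in ids) for (i in ids) {
    if (m[i, k]) m[i, ] <- m[i, ] | m[k, ]
  }
  m
}

read_sidecar <- function(dir, tag, ext, cap = Inf) {
  path <- file.path(dir, paste0(tag, ".", ext))
  if (!file.exists(path)) return("")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.finite(cap) && nchar(txt, type = "bytes") > cap) {
    txt <- paste0(substr(txt, 1, cap), "\n[truncated]")
  }
  txt
}

#' Parse a delimited batch file
#'
#' Batch submission reads a UTF-8 delimited text file whose first row
#' names parameter keys and whose subsequent rows each describe one job.
#' The delimiter is auto-detected between tab and comma unless fixed by
#' configuration.  A row with the wrong number of fields is an error that
#' names the offending (1-based) data row.
#'
#' @param batch file path or literal text.
#' @param delimiter `"\t"`, `","`, or NULL to auto-detect.
#' @return a data frame of character columns, one per header key.
#' @export
parse_batch_file <- function(batch, delimiter = NULL) {
  text <- if (length(batch) == 1 && file.exists(batch) && !dir.exists(batch)) {
    paste(readLines(batch, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(batch, collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("batch file has no header row")
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  }
  header <- strsplit(lines[1], delimiter, fixed = TRUE)[[1]]
  k <- length(header)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    fields <- strsplit(lines[i + 1], delimiter, fixed = TRUE)[[1]]
    if (length(fields) != k) {
      abort(sprintf("row %d: expected %d fields, got %d", i, k, length(fields)))
    }
    setNames(as.list(fields), header)
  })
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r) unlist(r))),
                       stringsAsFactors = FALSE)
  if (length(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), k), header),
                         stringsAsFactors = FALSE)
  } else {
    names(out) <- header
  }
  out
}

# precedence: explicit stage binding > user input > profile > default
resolve_stage_parameters <- function(sid, stage_content, tool_content,
                                     inputs, profile_values) {
  vals <- list()
  missing <- character()
  for (p in tool_content$parameters) {
    b <- stage_content$bindings[[p$key]]
    if (!is.null(b) && !identical(b, "__user_input__")) {
      vals[[p$key]] <- b
      next
    }
    scoped <- paste0(sid, ".", p$key)
    v <- inputs[[scoped]] %||% inputs[[p$key]] %||%
      profile_values[[scoped]] %||% profile_values[[p$key]] %||% p$default
    if (is.null(v)) {
      if (isTRUE(p$required)) missing <- c(missing, p$key)
      next
    }
    check_param_value(p$key, p$kind, unlist(p$choices), v)
    vals[[p$key]] <- v
  }
  if (length(missing)) {
    abort(sprintf("stage '%s': missing required parameter(s): %s",
                  sid, paste(missing, collapse = ", ")))
  }
  vals
}
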