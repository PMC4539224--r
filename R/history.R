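#' Persistent job history
#'
#' Every submitted job — completed, failed or cancelled — leaves a
#' permanent record: per-stage resolved parameters, both output streams,
#' exit statuses, timestamps and snapshot references, plus who the job
#' has been shared with.  The store sits behind a thin persistence
#' boundary (one JSON document per job under a directory) so a different
#' storage engine can substitute without touching the callers; streams
#' are capped at a configurable size with a truncation marker, and
#' timestamps are stored as ISO-8601 UTC.
#'
#' @param dir directory the records live in (created if needed).
#' @return `history_store()` returns a `HistoryStore` R6 object.
#' @export
history_store <- function(dir = tempfile("stageflow-history")) {
  HistoryStore$new(dir)
}

iso_time <- function(t) {
  if (is.null(t)) return(NULL)
  format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

#' @rdname history_store
#' @export
HistoryStore <- R6::R6Class("HistoryStore",
  public = list(
    #' @field dir storage directory.
    dir = NULL,

    #' @description Open (and create) a store.
    #' @param dir storage directory.
    initialize = function(dir) {
      self$dir <- dir
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    },

    #' @description Create the record for a newly submitted job.
    #' @param job a [JobRun].
    create_job = function(job) {
      rec <- list(job_id = job$job_id, workflow = job$workflow,
                  version = job$version, user = job$user,
                  status = job$status, created_at = iso_time(job$created_at),
                  finished_at = NULL, working_dir = job$working_dir,
                  resumed_from = job$resumed_from,
                  shared_with = list(), stages = list())
      private$write(rec)
      invisible(rec)
    },

    #' @description Store a terminal stage run.  Idempotent: re-storing
    #'   the same terminal state keeps a single entry.
    #' @param job_id job id (must exist).
    #' @param stage_run a terminal stage-run record.
    record_stage = function(job_id, stage_run) {
      if (!stage_run$state %in% STAGE_TERMINAL) {
        abort(sprintf("stage '%s' is not terminal (%s)",
                      stage_run$stage_id, stage_run$state))
      }
      rec <- private$read(job_id)
      rec$stages[[stage_run$stage_id]] <- list(
        stage_id = stage_run$stage_id,
        state = stage_run$state,
        exit_status = stage_run$exit_status,
        stdout = stage_run$stdout,
        stderr = stage_run$stderr,
        resolved_parameters = stage_run$resolved_parameters,
        snapshot_ref = stage_run$snapshot_ref,
        post_snapshot_ref = stage_run$post_snapshot_ref,
        started_at = iso_time(stage_run$started_at),
        finished_at = iso_time(stage_run$finished_at),
        carried = isTRUE(stage_run$carried))
      private$write(rec)
      invisible(rec$stages[[stage_run$stage_id]])
    },

    #' @description Record a job's terminal status.
    #' @param job a [JobRun].
    finalize_job = function(job) {
      rec <- private$read(job$job_id)
      rec$status <- job$status
      rec$finished_at <- iso_time(job$finished_at)
      private$write(rec)
      invisible(rec)
    },

    #' @description Full record of one job, access-checked.
    #' @param job_id job id.
    #' @param user reading user; must own the job or have it shared with
    #'   them (NULL skips the check).
    get_job = function(job_id, user = NULL) {
      rec <- private$read(job_id)
      if (!is.null(user) && !private$readable(rec, user)) {
        abort(sprintf("user '%s' may not read job '%s'", user, job_id))
      }
      rec
    },

    #' @description Does a record exist for this job?
    #' @param job_id job id.
    has_job = function(job_id) file.exists(private$path(job_id)),

    #' @description Remove a job's record.
    #' @param job_id job id.
    delete_job = function(job_id) {
      p <- private$path(job_id)
      if (!file.exists(p)) abort(sprintf("no history record for job '%s'", job_id))
      unlink(p)
      invisible(TRUE)
    },

    #' @description Share a job (read-only) with another user.
    #' @param job_id job id.
    #' @param owner acting user; must own the job.
    #' @param other_user recipient; may read the record and streams, but
    #'   not cancel, delete or re-share.
    share_job = function(job_id, owner, other_user) {
      rec <- private$read(job_id)
      if (!identical(owner, rec$user)) {
        abort(sprintf("user '%s' does not own job '%s' and may not share it",
                      owner, job_id))
      }
      rec$shared_with <- union(unlist(rec$shared_with), other_user)
      private$write(rec)
      invisible(rec)
    },

    #' @description Query the history as a tibble, newest first.  Filters
    #'   are conjunctive; `as_user` restricts to records that user may
    #'   read (own + shared).
    #' @param user filter: submitting user.
    #' @param workflow filter: workflow name.
    #' @param status filter: job status.
    #' @param from,to filter: created-at range (ISO strings or POSIXct).
    #' @param as_user visibility restriction.
    query = function(user = NULL, workflow = NULL, status = NULL,
                     from = NULL, to = NULL, as_user = NULL) {
      recs <- private$all()
      if (!is.null(as_user)) {
        recs <- Filter(function(r) private$readable(r, as_user), recs)
      }
      keep <- function(r) {
        (is.null(user) || identical(r$user, user)) &&
          (is.null(workflow) || identical(r$workflow, workflow)) &&
          (is.null(status) || identical(r$status, status)) &&
          (is.null(from) || r$created_at >= iso_coerce(from)) &&
          (is.null(to) || r$created_at <= iso_coerce(to))
      }
      recs <- Filter(keep, recs)
      out <- dplyr::bind_rows(lapply(recs, function(r) {
        tibble(job_id = r$job_id, workflow = r$workflow,
               version = r$version, user = r$user, status = r$status,
               created_at = r$created_at,
               finished_at = r$finished_at %||% NA_character_,
               n_stages = length(r$stages))
      }))
      if (nrow(out)) out <- dplyr::arrange(out, dplyr::desc(created_at))
      out
    }
  ),

  private = list(
    path = function(job_id) file.path(self$dir, paste0(job_id, ".json")),
    read = function(job_id) {
      p <- private$path(job_id)
      if (!file.exists(p)) abort(sprintf("no history record for job '%s'", job_id))
      jsonlite::fromJSON(read_text(p), simplifyVector = FALSE)
    },
    write = function(rec) {
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
                 private$path(rec$job_id), useBytes = TRUE)
    },
    all = function() {
      files <- list.files(self$dir, pattern = "\\.json$", full.names = TRUE)
      lapply(files, function(f) jsonlite::fromJSON(read_text(f), simplifyVector = FALSE))
    },
    readable = function(rec, user) {
      identical(user, rec$user) || user %in% unlist(rec$shared_with)
    }
  )
)

iso_coerce <- function(x) {
  if (inherits(x, "POSIXt")) iso_time(x) else as.character(x)
}

#' One polling tick of the background updater
#'
#' The production system keeps job history current by continuously
#' polling the resource manager; here the cadence is explicit — each call
#' performs one tick.  Every active job is stepped (statuses refreshed
#' from the backend, newly terminal stages recorded and their conditions
#' propagated).  If the backend is unreachable the records are left
#' untouched and a warning is raised.
#'
#' @param jm a [job_manager()].
#' @return tibble of the refreshed jobs' current statuses (possibly empty).
#' @export
poll_tick <- function(jm) {
  ids <- jm$active_jobs()
  out <- list()
  for (id in ids) {
    job <- jm$job(id)
    res <- tryCatch({ jm$step(job); TRUE },
                    backend_unavailable = function(e) FALSE,
                    error = function(e) {
                      if (inherits(e, "backend_unavailable")) FALSE else stop(e)
                    })
    if (!isTRUE(res)) {
      warning(sprintf("backend unavailable; job '%s' left untouched", id))
      next
    }
    out[[id]] <- tibble(job_id = id, status = job$status)
  }
  dplyr::bind_rows(out)
}
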