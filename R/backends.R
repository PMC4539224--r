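#' Resource-manager backend contract
#'
#' Cluster schedulers are reached through plugins.  Every backend inherits
#' from `ResourceBackend` and overrides its operations: submit a job
#' script, poll a job's status, cancel/hold/release, take a cluster
#' snapshot, and read/update queue and node settings.  Data flows back in
#' [typed_data_object()]s so the core never needs backend-specific
#' knowledge to render or compare values; an operation a plugin does not
#' provide raises a uniform `backend_not_supported` condition.
#'
#' @docType class
#' @export
ResourceBackend <- R6::R6Class("ResourceBackend",
  public = list(
    #' @field name backend name used for selection in configuration.
    name = "abstract",

    #' @description Submit a job script. Concrete backends override.
    #' @param script_text script body.
    #' @param working_dir directory to execute in.
    #' @param tag stable tag used for sidecar file names.
    submit = function(script_text, working_dir, tag = "job") {
      backend_not_supported(self$name, "submit")
    },

    #' @description Status of a submitted job.
    #' @param backend_job_id id returned by `submit()`.
    status = function(backend_job_id) backend_not_supported(self$name, "status"),

    #' @description Cancel a job.
    #' @param backend_job_id id returned by `submit()`.
    cancel = function(backend_job_id) backend_not_supported(self$name, "cancel"),

    #' @description Hold a job.
    #' @param backend_job_id id returned by `submit()`.
    hold = function(backend_job_id) backend_not_supported(self$name, "hold"),

    #' @description Release a held job.
    #' @param backend_job_id id returned by `submit()`.
    release = function(backend_job_id) backend_not_supported(self$name, "release"),

    #' @description Aggregate cluster state (see [cluster_status()]).
    cluster_snapshot = function() backend_not_supported(self$name, "cluster_snapshot"),

    #' @description Read scheduler settings (queues, nodes).
    settings = function() backend_not_supported(self$name, "settings"),

    #' @description Update scheduler settings.
    #' @param new named list merged into the current settings.
    update_settings = function(new) backend_not_supported(self$name, "update_settings")
  )
)

read_exit_code <- function(path) {
  if (!file.exists(path)) return(NA_integer_)
  suppressWarnings(as.integer(readLines(path, warn = FALSE)[1]))
}

backend_not_supported <- function(backend, op) {
  rlang::abort(sprintf("operation '%s' not supported by plugin '%s'", op, backend),
               class = "backend_not_supported")
}

#' Metadata-carrying value container returned by backend plugins
#'
#' Plugins populate these objects with scheduler data; the metadata names
#' every key's label and value kind (`text`, `integer`, `duration`,
#' `bytes`, `state`) so consumers can display or compare values without
#' backend-specific knowledge.
#'
#' @param values named list of values.
#' @param metadata named list, one entry per value key, each a
#'   `list(label =, value_kind =)`.
#' @param source backend name the data came from.
#' @return a `typed_data_object`.
#' @export
typed_data_object <- function(values = list(), metadata = list(), source = "unknown") {
  uncovered <- setdiff(names(values), names(metadata))
  if (length(uncovered)) {
    abort(sprintf("metadata missing for key(s): %s", paste(uncovered, collapse = ", ")))
  }
  kinds <- vapply(metadata, `[[`, character(1), "value_kind")
  bad <- setdiff(kinds, c("text", "integer", "duration", "bytes", "state"))
  if (length(bad)) abort(sprintf("unknown value kind(s): %s", paste(bad, collapse = ", ")))
  structure(list(values = values, metadata = metadata, source = source),
            class = "typed_data_object")
}

#' @export
tidy.typed_data_object <- function(x, ...) {
  tibble(
    key = names(x$values),
    label = unname(vapply(x$metadata[names(x$values)], `[[`, character(1), "label")),
    value_kind = unname(vapply(x$metadata[names(x$values)], `[[`, character(1), "value_kind")),
    value = unname(vapply(x$values, function(v) paste(format(v), collapse = ","),
                          character(1))),
    source = x$source
  )
}

#' One job's status as reported by a backend
#'
#' @param backend_job_id scheduler-side job id.
#' @param state one of `queued`, `running`, `held`, `completed`,
#'   `exiting`, `cancelled`, `unknown`.  Codes a dialect does not know map
#'   to `unknown`, never to an error.
#' @param exit_status integer exit code, or `NULL` while unavailable.
#' @param resources_used a [typed_data_object()].
#' @param raw the original status text block, preserved verbatim.
#' @return a `job_status_record`.
#' @export
job_status_record <- function(backend_job_id, state, exit_status = NULL,
                              resources_used = typed_data_object(), raw = "") {
  state <- match.arg(state, c("queued", "running", "held", "completed",
                              "exiting", "cancelled", "unknown"))
  structure(
    list(backend_job_id = backend_job_id, state = state,
         exit_status = if (is.null(exit_status)) NULL else as.integer(exit_status),
         resources_used = resources_used, raw = raw),
    class = "job_status_record"
  )
}

#' Aggregate cluster state for the dashboard
#'
#' @param nodes_online,nodes_offline node counts.
#' @param cores_total,cores_busy core counts; busy never exceeds total.
#' @param jobs_running,jobs_queued job counts.
#' @param disk_available bytes of free shared storage.
#' @param nodes per-node detail tibble (name, state, cores, cores_busy).
#' @return a `cluster_status` object.
#' @export
cluster_status <- function(nodes_online = 0, nodes_offline = 0,
                           cores_total = 0, cores_busy = 0,
                           jobs_running = 0, jobs_queued = 0,
                           disk_available = NA_real_,
                           nodes = tibble(name = character(), state = character(),
                                          cores = integer(), cores_busy = integer())) {
  if (cores_busy > cores_total) abort("cores_busy cannot exceed cores_total")
  structure(
    list(nodes_online = as.integer(nodes_online),
         nodes_offline = as.integer(nodes_offline),
         cores_total = as.integer(cores_total), cores_busy = as.integer(cores_busy),
         jobs_running = as.integer(jobs_running), jobs_queued = as.integer(jobs_queued),
         disk_available = disk_available, nodes = nodes),
    class = "cluster_status"
  )
}

#' @export
glance.cluster_status <- function(x, ...) {
  tibble(nodes_online = x$nodes_online, nodes_offline = x$nodes_offline,
         cores_total = x$cores_total, cores_busy = x$cores_busy,
         jobs_running = x$jobs_running, jobs_queued = x$jobs_queued,
         disk_available = x$disk_available)
}

#' @export
print.cluster_status <- function(x, ...) {
  cat(sprintf("<cluster_status> %d/%d nodes online, %d/%d cores busy, %d running / %d queued\n",
              x$nodes_online, x$nodes_online + x$nodes_offline,
              x$cores_busy, x$cores_total, x$jobs_running, x$jobs_queued))
  invisible(x)
}

#' Local subprocess backend
#'
#' Executes job scripts as local subprocesses: each submission runs in the
#' job's working directory, stdout/stderr are captured to
#' `<tag>.out`/`<tag>.err` sidecars and the exit code is written to
#' `<tag>.exit` when the process finishes.  Cancellation kills the process
#' and leaves no exit sidecar.  This backend is the engine's test double
#' for a cluster scheduler, but is also a perfectly good way to run small
#' workflows on one machine.
#'
#' @return a `LocalBackend` R6 object (inherits [ResourceBackend]).
#' @examples
#' \dontrun{
#' b <- local_backend()
#' d <- tempfile(); dir.create(d)
#' id <- b$submit("exit 5", d, tag = "stage_A")
#' while (b$status(id)$state == "running") Sys.sleep(0.01)
#' b$status(id)$exit_status  # 5
#' }
#' @export
local_backend <- function() LocalBackend$new()

#' @rdname local_backend
#' @export
LocalBackend <- R6::R6Class("LocalBackend", inherit = ResourceBackend,
  public = list(
    #' @field name backend name.
    name = "local",

    #' @description Create the backend.
    initialize = function() {
      private$jobs <- new.env(parent = emptyenv())
    },

    #' @description Run a script as a subprocess in `working_dir`.
    #' @param script_text POSIX shell script body.
    #' @param working_dir existing directory to run in.
    #' @param tag sidecar name prefix.
    submit = function(script_text, working_dir, tag = "job") {
      if (!dir.exists(working_dir)) {
        abort(sprintf("working directory '%s' does not exist", working_dir))
      }
      run_dir <- file.path(working_dir, ".run")
      dir.create(run_dir, showWarnings = FALSE)
      payload <- file.path(run_dir, paste0(tag, ".sh"))
      writeLines(script_text, payload)
      wrapper <- sprintf("sh %s > %s.out 2> %s.err; echo $? > %s.exit",
                         shQuote(payload), tag, tag, tag)
      p <- processx::process$new("sh", c("-c", wrapper), wd = working_dir)
      id <- sf_next_id("local")
      assign(id, list(process = p, dir = working_dir, tag = tag,
                      cancelled = FALSE, started = Sys.time()),
             envir = private$jobs)
      id
    },

    #' @description Lifecycle status: queued -> running -> completed, or
    #'   cancelled; exit code read from the `.exit` sidecar.
    #' @param backend_job_id id from `submit()`.
    status = function(backend_job_id) {
      j <- private$get(backend_job_id)
      exit_file <- file.path(j$dir, paste0(j$tag, ".exit"))
      elapsed <- as.numeric(difftime(Sys.time(), j$started, units = "secs"))
      used <- typed_data_object(
        list(walltime = round(elapsed, 3)),
        list(walltime = list(label = "Elapsed time", value_kind = "duration")),
        source = "local")
      raw <- sprintf("local job %s (%s)", backend_job_id, j$tag)
      if (j$cancelled) {
        return(job_status_record(backend_job_id, "cancelled",
                                 resources_used = used, raw = raw))
      }
      code <- read_exit_code(exit_file)
      if (!is.na(code)) {
        return(job_status_record(backend_job_id, "completed", exit_status = code,
                                 resources_used = used, raw = raw))
      }
      if (j$process$is_alive()) {
        st <- if (private$is_stopped(j)) "held" else "running"
        return(job_status_record(backend_job_id, st, resources_used = used, raw = raw))
      }
      # the process is gone but the sidecar may not have hit the filesystem
      # yet; give it a grace period before declaring the job aborted
      for (i in 1:50) {
        Sys.sleep(0.01)
        code <- read_exit_code(exit_file)
        if (!is.na(code)) {
          return(job_status_record(backend_job_id, "completed", exit_status = code,
                                   resources_used = used, raw = raw))
        }
      }
      # died without writing a sidecar (killed externally)
      job_status_record(backend_job_id, "unknown", resources_used = used, raw = raw)
    },

    #' @description Kill the subprocess; no exit sidecar is written.
    #' @param backend_job_id id from `submit()`.
    cancel = function(backend_job_id) {
      j <- private$get(backend_job_id)
      if (j$process$is_alive()) j$process$kill()
      j$cancelled <- TRUE
      assign(backend_job_id, j, envir = private$jobs)
      invisible(TRUE)
    },

    #' @description Suspend the subprocess (SIGSTOP).
    #' @param backend_job_id id from `submit()`.
    hold = function(backend_job_id) {
      j <- private$get(backend_job_id)
      tools::pskill(j$process$get_pid(), 19)  # SIGSTOP
      j$stopped <- TRUE
      assign(backend_job_id, j, envir = private$jobs)
      invisible(TRUE)
    },

    #' @description Resume a suspended subprocess (SIGCONT).
    #' @param backend_job_id id from `submit()`.
    release = function(backend_job_id) {
      j <- private$get(backend_job_id)
      tools::pskill(j$process$get_pid(), 18)  # SIGCONT
      j$stopped <- FALSE
      assign(backend_job_id, j, envir = private$jobs)
      invisible(TRUE)
    },

    #' @description Single-machine cluster snapshot.
    cluster_snapshot = function() {
      ids <- ls(private$jobs)
      alive <- sum(vapply(ids, function(i) {
        j <- get(i, envir = private$jobs)
        !j$cancelled && j$process$is_alive()
      }, logical(1)))
      cores <- max(1L, parallel::detectCores())
      cluster_status(
        nodes_online = 1, nodes_offline = 0,
        cores_total = cores, cores_busy = min(cores, alive),
        jobs_running = alive, jobs_queued = 0,
        disk_available = NA_real_,
        nodes = tibble(name = "localhost", state = "free",
                       cores = cores, cores_busy = as.integer(min(cores, alive))))
    },

    #' @description Local settings (no scheduler; empty passthrough store).
    settings = function() private$conf,

    #' @description Update the passthrough settings store.
    #' @param new named list merged into the current settings.
    update_settings = function(new) {
      private$conf <- modifyList(private$conf, new)
      invisible(private$conf)
    }
  ),
  private = list(
    jobs = NULL,
    conf = list(),
    get = function(id) {
      if (!exists(id, envir = private$jobs)) abort(sprintf("unknown backend job '%s'", id))
      get(id, envir = private$jobs)
    },
    is_stopped = function(j) isTRUE(j$stopped)
  )
)

#' Scheduler-dialect backends (Torque / SLURM / UGE stub)
#'
#' These plugins generate dialect job scripts and parse the scheduler's
#' status text; their `submit()` shells out to `qsub`/`sbatch` and raises
#' a backend-unavailable error when the scheduler's commands are not
#' installed, so the engine's tests run entirely on the local backend.
#' The UGE backend is a deliberate stub demonstrating the plugin
#' contract: every operation raises the uniform not-supported signal.
#'
#' @param dialect `"torque"` or `"slurm"`.
#' @return a [ResourceBackend] subclass instance.
#' @export
scheduler_backend <- function(dialect = c("torque", "slurm")) {
  dialect <- match.arg(dialect)
  SchedulerBackend$new(dialect)
}

#' @rdname scheduler_backend
#' @export
SchedulerBackend <- R6::R6Class("SchedulerBackend", inherit = ResourceBackend,
  public = list(
    #' @field name dialect name.
    name = NULL,

    #' @description Create a dialect backend.
    #' @param dialect `"torque"` or `"slurm"`.
    initialize = function(dialect) {
      self$name <- dialect
      private$submit_cmd <- if (dialect == "torque") "qsub" else "sbatch"
      private$status_cmd <- if (dialect == "torque") "qstat" else "scontrol"
    },

    #' @description Submit via the scheduler's submission command.
    #' @param script_text job script (already carrying directives).
    #' @param working_dir directory to submit from.
    #' @param tag job tag.
    submit = function(script_text, working_dir, tag = "job") {
      if (Sys.which(private$submit_cmd) == "") {
        abort(sprintf("backend '%s' unavailable: '%s' not found on PATH",
                      self$name, private$submit_cmd),
              class = "backend_unavailable")
      }
      script <- file.path(working_dir, paste0(tag, ".job"))
      writeLines(script_text, script)
      out <- system2(private$submit_cmd, shQuote(script), stdout = TRUE)
      trimws(out[1])
    },

    #' @description Parse `qstat -f` / `scontrol show job` output for one job.
    #' @param backend_job_id scheduler job id.
    status = function(backend_job_id) {
      if (Sys.which(private$status_cmd) == "") {
        abort(sprintf("backend '%s' unavailable: '%s' not found on PATH",
                      self$name, private$status_cmd),
              class = "backend_unavailable")
      }
      args <- if (self$name == "torque") c("-f", backend_job_id) else
        c("show", "job", backend_job_id)
      txt <- paste(system2(private$status_cmd, args, stdout = TRUE), collapse = "\n")
      recs <- parse_status_text(txt, self$name)
      if (length(recs) == 0) {
        return(job_status_record(backend_job_id, "unknown", raw = txt))
      }
      recs[[1]]
    },

    #' @description Queue/node settings passthrough store.
    settings = function() private$conf,

    #' @description Update the passthrough settings store.
    #' @param new named list merged in.
    update_settings = function(new) {
      private$conf <- modifyList(private$conf, new)
      invisible(private$conf)
    }
  ),
  private = list(submit_cmd = NULL, status_cmd = NULL, conf = list())
)

#' @rdname scheduler_backend
#' @export
UgeBackend <- R6::R6Class("UgeBackend", inherit = ResourceBackend,
  public = list(
    #' @field name backend name.
    name = "uge"
  )
)

#' Load a backend by name, including plugins from a directory
#'
#' Built-in backends (`local`, `torque`, `slurm`, `uge`) are returned
#' directly.  Any other name is looked up in the configured plugin
#' directory: a file `<name>.R` there must define a function
#' `backend_<name>()` returning a [ResourceBackend]; dropping such a file
#' into the directory and naming the backend in the configuration is all
#' it takes to add scheduler support — no core code changes.
#'
#' @param name backend name from configuration.
#' @param config a [stageflow_config()] list (used for `plugin_dir`).
#' @return a [ResourceBackend] instance.
#' @export
load_backend <- function(name, config = stageflow_config()) {
  switch(name,
    local = local_backend(),
    torque = scheduler_backend("torque"),
    slurm = scheduler_backend("slurm"),
    uge = UgeBackend$new(),
    {
      plugin_file <- file.path(config$plugin_dir %||% ".", paste0(name, ".R"))
      if (!file.exists(plugin_file)) {
        abort(sprintf("unknown backend '%s' and no plugin file '%s'", name, plugin_file))
      }
      env <- new.env(parent = asNamespace("stageflow"))
      sys.source(plugin_file, envir = env)
      ctor <- get0(paste0("backend_", name), envir = env, mode = "function")
      if (is.null(ctor)) {
        abort(sprintf("plugin file '%s' does not define backend_%s()", plugin_file, name))
      }
      b <- ctor()
      if (!inherits(b, "ResourceBackend")) {
        abort(sprintf("backend_%s() must return a ResourceBackend", name))
      }
      b
    }
  )
}

#' Runtime configuration
#'
#' Mirrors a settings file: which backend to use, where plugins live, the
#' polling cadence of the background updater, the root of the managed
#' working-directory hierarchy, and engine switches.
#'
#' @param path optional YAML file to read.
#' @param ... named overrides of individual settings.
#' @return a named list with class `stageflow_config`.
#' @export
stageflow_config <- function(path = NULL, ...) {
  defaults <- list(
    backend = "local",
    plugin_dir = "plugins",
    poll_interval = 5,          # seconds, background updater cadence
    workdir_root = file.path(tempdir(), "stageflow-jobs"),
    snapshot_sequential = TRUE, # post-stage snapshots for history
    batch_delimiter = NULL,     # NULL = auto-detect tab/comma
    max_workers = 2L,
    stream_cap = 64 * 1024      # bytes kept per stream in history
  )
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "stageflow_config")
}
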