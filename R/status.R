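#' Parse scheduler status text into job status records
#'
#' Reads the long-form status output of a scheduler — `qstat -f`-style
#' blocks for Torque, `scontrol show job`-style blocks for SLURM — into a
#' list of [job_status_record()]s.  Parsing is best-effort: one record
#' per job block, unknown state codes map to `unknown`, and a block that
#' cannot be parsed at all still yields a record with `state = "unknown"`
#' and the raw text retained, never an exception.
#'
#' @param text status command output (blocks separated by blank lines).
#' @param dialect `"torque"` or `"slurm"`.
#' @return list of [job_status_record()]s (possibly empty).
#' @export
parse_status_text <- function(text, dialect = c("torque", "slurm")) {
  dialect <- match.arg(dialect)
  blocks <- split_blocks(text)
  lapply(blocks, function(b) {
    tryCatch(
      if (dialect == "torque") parse_torque_block(b) else parse_slurm_block(b),
      error = function(e) job_status_record(NA_character_, "unknown", raw = b))
  })
}

split_blocks <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(list())
  chunks <- strsplit(paste(text, collapse = "\n"), "\n[[:space:]]*\n")[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  as.list(chunks)
}

TORQUE_STATES <- c(Q = "queued", R = "running", H = "held", C = "completed",
                   E = "exiting", W = "queued", S = "held")

parse_torque_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  idline <- grep("^\\s*Job Id:", lines, value = TRUE)
  if (length(idline) == 0) return(job_status_record(NA_character_, "unknown", raw = block))
  id <- trimws(sub("^\\s*Job Id:", "", idline[1]))
  fields <- parse_kv(lines, sep = " = ")
  state_code <- fields[["job_state"]] %||% ""
  state <- unname(TORQUE_STATES[state_code])
  if (is.na(state) || is.null(state)) state <- "unknown"
  exit <- fields[["exit_status"]]
  used <- fields[grep("^resources_used\\.", names(fields))]
  names(used) <- sub("^resources_used\\.", "", names(used))
  job_status_record(
    id, state,
    exit_status = if (!is.null(exit)) as.integer(exit),
    resources_used = used_tdo(used, "torque"),
    raw = block)
}

SLURM_STATES <- c(RUNNING = "running", PENDING = "queued", SUSPENDED = "held",
                  COMPLETED = "completed", FAILED = "completed",
                  CANCELLED = "cancelled", COMPLETING = "exiting",
                  TIMEOUT = "completed")

parse_slurm_block <- function(block) {
  tokens <- regmatches(block, gregexpr("[A-Za-z:/_.]+=[^ \n]*", block))[[1]]
  kv <- strsplit(tokens, "=", fixed = TRUE)
  fields <- setNames(
    as.list(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))),
    vapply(kv, `[[`, character(1), 1))
  if (!"JobId" %in% names(fields)) {
    return(job_status_record(NA_character_, "unknown", raw = block))
  }
  state <- unname(SLURM_STATES[fields[["JobState"]] %||% ""])
  if (is.na(state) || is.null(state)) state <- "unknown"
  exit <- NULL
  if (!is.null(fields[["ExitCode"]]) && grepl("^[0-9]+:[0-9]+$", fields[["ExitCode"]])) {
    exit <- as.integer(sub(":.*$", "", fields[["ExitCode"]]))
  }
  used <- fields[names(fields) %in% c("RunTime", "NumCPUs", "NumNodes")]
  job_status_record(fields[["JobId"]], state, exit_status = exit,
                    resources_used = used_tdo(used, "slurm"),
                    raw = block)
}

parse_kv <- function(lines, sep) {
  kv <- lines[grepl(sep, lines, fixed = TRUE)]
  parts <- strsplit(trimws(kv), sep, fixed = TRUE)
  vals <- lapply(parts, function(x) paste(x[-1], collapse = sep))
  setNames(vals, vapply(parts, `[[`, character(1), 1))
}

USED_KINDS <- c(cput = "duration", walltime = "duration", RunTime = "duration",
                mem = "bytes", vmem = "bytes",
                NumCPUs = "integer", NumNodes = "integer", energy_used = "integer")

used_tdo <- function(used, source) {
  if (length(used) == 0) return(typed_data_object(source = source))
  kinds <- unname(USED_KINDS[names(used)])
  kinds[is.na(kinds)] <- "text"
  typed_data_object(
    values = as.list(used),
    metadata = setNames(
      Map(function(k, kind) list(label = k, value_kind = kind), names(used), kinds),
      names(used)),
    source = source)
}

#' Tabulate parsed status records
#'
#' @param records list of [job_status_record()]s.
#' @return a tibble with one row per record.
#' @export
status_table <- function(records) {
  dplyr::bind_rows(lapply(records, function(r) {
    tibble(backend_job_id = as.character(r$backend_job_id %||% NA_character_),
           state = r$state,
           exit_status = if (is.null(r$exit_status)) NA_integer_ else r$exit_status)
  }))
}

#' Aggregate a cluster snapshot from status text
#'
#' Builds the dashboard's [cluster_status()] from the three status texts
#' an administrator would consult: node status (`pbsnodes -a` style for
#' Torque, `scontrol show node` style for SLURM), the job queue (same
#' format as [parse_status_text()]), and a `df`-style disk report for the
#' shared storage.
#'
#' @param node_text node-status text.
#' @param queue_text job-queue status text.
#' @param disk_text `df -B1`-style output for the shared filesystem
#'   (optional).
#' @param dialect `"torque"` or `"slurm"`.
#' @return a [cluster_status()].
#' @export
cluster_snapshot_from_fixtures <- function(node_text, queue_text, disk_text = "",
                                           dialect = c("torque", "slurm")) {
  dialect <- match.arg(dialect)
  nodes <- if (dialect == "torque") parse_torque_nodes(node_text) else
    parse_slurm_nodes(node_text)
  jobs <- parse_status_text(queue_text, dialect)
  states <- vapply(jobs, `[[`, character(1), "state")
  disk <- parse_disk_text(disk_text)
  cluster_status(
    nodes_online = sum(nodes$online),
    nodes_offline = sum(!nodes$online),
    cores_total = sum(nodes$cores),
    cores_busy = sum(nodes$cores_busy),
    jobs_running = sum(states == "running"),
    jobs_queued = sum(states %in% c("queued", "held")),
    disk_available = disk,
    nodes = tibble(name = nodes$name,
                   state = ifelse(nodes$online, "online", "offline"),
                   cores = as.integer(nodes$cores),
                   cores_busy = as.integer(nodes$cores_busy)))
}

parse_torque_nodes <- function(text) {
  blocks <- split_blocks(text)
  rows <- lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    name <- trimws(lines[1])
    fields <- parse_kv(lines[-1], sep = " = ")
    state <- fields[["state"]] %||% "unknown"
    jobs <- fields[["jobs"]] %||% ""
    busy <- if (nzchar(trimws(jobs))) {
      length(strsplit(jobs, ",", fixed = TRUE)[[1]])
    } else 0L
    list(name = name,
         online = !grepl("down|offline", state),
         cores = as.integer(fields[["np"]] %||% 0),
         cores_busy = busy)
  })
  list(name = vapply(rows, `[[`, character(1), "name"),
       online = vapply(rows, `[[`, logical(1), "online"),
       cores = vapply(rows, `[[`, integer(1), "cores"),
       cores_busy = vapply(rows, function(r) as.integer(r$cores_busy), integer(1)))
}

parse_slurm_nodes <- function(text) {
  blocks <- split_blocks(text)
  rows <- lapply(blocks, function(b) {
    tokens <- regmatches(b, gregexpr("[A-Za-z]+=[^ \n]*", b))[[1]]
    kv <- strsplit(tokens, "=", fixed = TRUE)
    fields <- setNames(as.list(vapply(kv, function(x) x[2], character(1))),
                       vapply(kv, `[[`, character(1), 1))
    state <- fields[["State"]] %||% "UNKNOWN"
    list(name = fields[["NodeName"]] %||% "?",
         online = !grepl("DOWN|DRAIN", state),
         cores = as.integer(fields[["CPUTot"]] %||% 0),
         cores_busy = as.integer(fields[["CPUAlloc"]] %||% 0))
  })
  list(name = vapply(rows, `[[`, character(1), "name"),
       online = vapply(rows, `[[`, logical(1), "online"),
       cores = vapply(rows, `[[`, integer(1), "cores"),
       cores_busy = vapply(rows, `[[`, integer(1), "cores_busy"))
}

parse_disk_text <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  data <- grep("^/", lines, value = TRUE)
  if (length(data) == 0) return(NA_real_)
  fields <- strsplit(trimws(data[1]), "[[:space:]]+")[[1]]
  if (length(fields) < 4) return(NA_real_)
  suppressWarnings(as.numeric(fields[4]))
}
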