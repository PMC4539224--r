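#' Generate a scheduler job script
#'
#' Translates a [resource_request()] and a resolved command into a job
#' script in the requested scheduler dialect.  Torque scripts carry
#' `#PBS` directives (`-l nodes=N:ppn=C`, `-l mem=...mb`,
#' `-l walltime=HH:MM:SS`, `-q`); SLURM scripts carry `#SBATCH`
#' directives (`--nodes`, `--ntasks-per-node`, `--mem` in MB, `--time`,
#' `--partition`).  Memory is emitted as integer megabytes and walltime
#' as `HH:MM:SS` in both dialects.  When `exit_path` is given, the
#' command is wrapped so its exit code is written to that sidecar file —
#' schedulers do not uniformly report per-stage exit codes, and the
#' engine's conditional edges need the exact code.
#'
#' @param command resolved command line to run.
#' @param resources a [resource_request()].
#' @param dialect `"torque"` or `"slurm"`.
#' @param name job name for the scheduler.
#' @param stdout_path,stderr_path stream destinations.
#' @param exit_path optional sidecar file to write the exit code to.
#' @return the script text (single string).
#' @examples
#' cat(generate_job_script("echo hi", resource_request(1, 2, 4 * 1024^2, 60),
#'                         "torque"))
#' @seealso [parse_job_script()] recovers the request from a script.
#' @export
generate_job_script <- function(command, resources,
                                dialect = c("torque", "slurm"),
                                name = "stageflow-job",
                                stdout_path = NULL, stderr_path = NULL,
                                exit_path = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(resources, "resource_request"))
  mem_mb <- as.integer(round(resources$memory / 1024^2))
  if (mem_mb < 1) mem_mb <- 1L
  wt <- format_walltime(resources$walltime)

  directives <- if (dialect == "torque") {
    c(sprintf("#PBS -N %s", name),
      sprintf("#PBS -l nodes=%d:ppn=%d", resources$nodes, resources$cores_per_node),
      sprintf("#PBS -l mem=%dmb", mem_mb),
      sprintf("#PBS -l walltime=%s", wt),
      if (!is.null(resources$queue)) sprintf("#PBS -q %s", resources$queue),
      if (!is.null(stdout_path)) sprintf("#PBS -o %s", stdout_path),
      if (!is.null(stderr_path)) sprintf("#PBS -e %s", stderr_path))
  } else {
    c(sprintf("#SBATCH --job-name=%s", name),
      sprintf("#SBATCH --nodes=%d", resources$nodes),
      sprintf("#SBATCH --ntasks-per-node=%d", resources$cores_per_node),
      sprintf("#SBATCH --mem=%d", mem_mb),
      sprintf("#SBATCH --time=%s", wt),
      if (!is.null(resources$queue)) sprintf("#SBATCH --partition=%s", resources$queue),
      if (!is.null(stdout_path)) sprintf("#SBATCH --output=%s", stdout_path),
      if (!is.null(stderr_path)) sprintf("#SBATCH --error=%s", stderr_path))
  }
  body <- if (is.null(exit_path)) {
    command
  } else {
    c(sprintf("( %s )", command),
      sprintf("echo $? > %s", exit_path))
  }
  paste(c("#!/bin/sh", directives, "", body, ""), collapse = "\n")
}

format_walltime <- function(seconds) {
  seconds <- as.integer(round(seconds))
  sprintf("%02d:%02d:%02d", seconds %/% 3600, (seconds %% 3600) %/% 60, seconds %% 60)
}

parse_walltime <- function(text) {
  parts <- as.integer(strsplit(text, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3 || anyNA(parts)) abort(sprintf("bad walltime '%s'", text))
  parts[1] * 3600 + parts[2] * 60 + parts[3]
}

#' Recover the resource request from a generated job script
#'
#' The inverse of [generate_job_script()]: reads the dialect directives
#' back into a [resource_request()].  Memory comes back in bytes (from
#' the integer-MB directive) and walltime in seconds, so a request whose
#' memory is a whole number of megabytes round-trips exactly.
#'
#' @param script_text job script text.
#' @param dialect `"torque"` or `"slurm"`.
#' @return a [resource_request()].
#' @export
parse_job_script <- function(script_text, dialect = c("torque", "slurm")) {
  dialect <- match.arg(dialect)
  lines <- strsplit(script_text, "\n", fixed = TRUE)[[1]]
  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(pattern, "\\1", hit[1])
  }
  if (dialect == "torque") {
    nodes_ppn <- grab("^#PBS -l nodes=([0-9]+:ppn=[0-9]+)$")
    if (is.null(nodes_ppn)) abort("no nodes/ppn directive found")
    nn <- as.integer(sub(":ppn=.*$", "", nodes_ppn))
    cc <- as.integer(sub("^.*:ppn=", "", nodes_ppn))
    mem <- grab("^#PBS -l mem=([0-9]+)mb$")
    wt <- grab("^#PBS -l walltime=([0-9:]+)$")
    q <- grab("^#PBS -q (.+)$")
  } else {
    nn <- as.integer(grab("^#SBATCH --nodes=([0-9]+)$"))
    cc <- as.integer(grab("^#SBATCH --ntasks-per-node=([0-9]+)$"))
    mem <- grab("^#SBATCH --mem=([0-9]+)$")
    wt <- grab("^#SBATCH --time=([0-9:]+)$")
    q <- grab("^#SBATCH --partition=(.+)$")
  }
  if (is.null(mem) || is.null(wt) || is.na(nn) || is.na(cc)) {
    abort(sprintf("script is not a complete %s job script", dialect))
  }
  resource_request(nodes = nn, cores_per_node = cc,
                   memory = as.numeric(mem) * 1024^2,
                   walltime = parse_walltime(wt), queue = q)
}
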