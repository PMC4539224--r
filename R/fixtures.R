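#' Deterministic test-fixture generators
#'
#' Everything the test suite runs against is generated here, from
#' nothing but a pattern name and a seed: the canonical branching
#' patterns (a success/failure fork, an exit-code fork, the
#' diamond-with-tail five-stage workflow), a six-stage pipeline skeleton
#' with two independent preparation stages, linear chains, random DAGs
#' for oracle comparisons, and scheduler status text with known ground
#' truth.  Stage scripts are plain POSIX shell: they sleep a planned
#' delay, write a marker file, and exit with a planned code.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STEP_SCRIPT <- paste(
  "#!/bin/sh",
  "# sleep a planned delay, leave a marker, exit with a planned code",
  "d=\"$1\"; c=\"$2\"; m=\"$3\"",
  "if [ \"$d\" != \"0\" ]; then sleep \"$d\"; fi",
  "echo \"stage $m ran\"",
  "touch \"$m.done\"",
  "exit \"$c\"",
  "", sep = "\n")

step_tool <- function() {
  tool_definition(
    "step", "sh ${SCRIPTS}/run.sh ${delay} ${code} ${marker}",
    parameters = list(
      parameter_spec("delay", "Delay before exiting (s)", kind = "number", default = 0),
      parameter_spec("code", "Exit code", kind = "number", default = 0),
      parameter_spec("marker", "Marker file stem", kind = "text", default = "stage")),
    description = "controllable placeholder stage: sleeps, touches a marker, exits",
    expected_outputs = "*.done",
    resources = resource_request(1, 1, 256 * 1024^2, 600),
    scripts = c("run.sh" = STEP_SCRIPT))
}

#' The dependency structure of a fixture pattern
#'
#' @param pattern one of `"fig4a"` (A forks to B on success, C on
#'   failure), `"fig4b"` (A forks to B on exit 1, C on exit 2),
#'   `"fig4c"` (the diamond with an exit-5 tail:
#'   A -> \{B, C\} -> D -> E), `"fig12_shape"` (stages s1 and s2
#'   independent, then s3 -> s4 -> s5 -> s6 sequential),
#'   `"linear"` (a chain of `n` stages), or `"random_dag"`.
#' @param n number of stages (`linear`, `random_dag`).
#' @param edge_p edge probability (`random_dag`).
#' @param seed RNG seed (`random_dag`); the same seed always produces
#'   the identical graph, acyclic by construction (edges only run from
#'   lower to higher index).
#' @return list with `stage_ids` and `edges` (list of
#'   parent/child/condition/code).
#' @export
fixture_pattern <- function(pattern, n = 3, edge_p = 0.3, seed = 1) {
  edge <- function(p, c, cond = "on_success", code = NULL) {
    list(parent = p, child = c, condition = cond, code = code)
  }
  switch(pattern,
    fig4a = list(
      stage_ids = c("A", "B", "C"),
      edges = list(edge("A", "B"), edge("A", "C", "on_fail"))),
    fig4b = list(
      stage_ids = c("A", "B", "C"),
      edges = list(edge("A", "B", "on_exit_code", 1L),
                   edge("A", "C", "on_exit_code", 2L))),
    fig4c = list(
      stage_ids = c("A", "B", "C", "D", "E"),
      edges = list(edge("A", "B"), edge("A", "C"),
                   edge("B", "D"), edge("C", "D"),
                   edge("D", "E", "on_exit_code", 5L))),
    fig12_shape = list(
      stage_ids = paste0("s", 1:6),
      edges = list(edge("s1", "s3"), edge("s2", "s3"),
                   edge("s3", "s4"), edge("s4", "s5"), edge("s5", "s6"))),
    linear = list(
      stage_ids = sprintf("s%02d", seq_len(n)),
      edges = if (n > 1) {
        lapply(seq_len(n - 1), function(i) {
          edge(sprintf("s%02d", i), sprintf("s%02d", i + 1))
        })
      } else list()),
    random_dag = with_seed(seed, {
      ids <- sprintf("s%02d", seq_len(n))
      edges <- list()
      if (n > 1) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
          if (runif(1) < edge_p) edges[[length(edges) + 1]] <- edge(ids[i], ids[j])
        }
      }
      list(stage_ids = ids, edges = edges)
    }),
    abort(sprintf("unknown fixture pattern '%s'", pattern)))
}

#' Build and publish a runnable fixture workflow
#'
#' Registers the controllable step tool and a workflow with the chosen
#' pattern's structure in `registry`, publishes both, and returns the
#' handles the engine needs.  Each stage's script exits with the planned
#' code after the planned delay and touches `<stage_id>.done` in the
#' working directory.
#'
#' @param pattern see [fixture_pattern()].
#' @param exit_codes named vector/list: stage id -> planned exit code
#'   (default 0 for unnamed stages).
#' @param delays named vector/list: stage id -> seconds to sleep.
#' @param checkpoints stage ids to flag as checkpoints (must be
#'   checkpoint-eligible).
#' @param user_params parameter keys to leave unbound (resolved from user
#'   inputs, profiles or the tool defaults at submission) instead of being
#'   fixed by the plan.
#' @param registry a [tool_registry()]; a fresh one is created if missing.
#' @param name workflow name in the registry.
#' @param user creating user.
#' @param n,edge_p,seed pattern arguments, see [fixture_pattern()].
#' @return list with `registry`, `workflow` (name), `version` (string).
#' @examples
#' fx <- fixture_workflow("fig4c", exit_codes = c(D = 5))
#' fx$registry$workflow_version(fx$workflow, fx$version)$content_hash
#' @export
fixture_workflow <- function(pattern, exit_codes = list(), delays = list(),
                             checkpoints = character(), registry = NULL,
                             name = paste0("fixture-", pattern), user = "local",
                             user_params = character(),
                             n = 3, edge_p = 0.3, seed = 1) {
  pat <- fixture_pattern(pattern, n = n, edge_p = edge_p, seed = seed)
  exit_codes <- as.list(exit_codes)
  delays <- as.list(delays)
  registry <- registry %||% tool_registry()
  if (!"step" %in% registry$tool_names()) {
    registry$create_tool(step_tool(), user = user)
    registry$publish_tool("step", "1.0.0", user = user)
  }
  stages <- lapply(pat$stage_ids, function(sid) {
    bindings <- list(
      delay = as.numeric(delays[[sid]] %||% 0),
      code = as.integer(exit_codes[[sid]] %||% 0L),
      marker = sid)
    stage(sid, "step", bindings = bindings[setdiff(names(bindings), user_params)],
          is_checkpoint = sid %in% checkpoints)
  })
  deps <- lapply(pat$edges, function(e) {
    stage_dependency(e$parent, e$child, e$condition, e$code)
  })
  state <- workflow_state(name, stages, deps,
                          description = sprintf("generated '%s' fixture", pattern))
  registry$create_workflow(state, user = user)
  ver <- registry$publish_workflow(name, "1.0.0", user = user)
  list(registry = registry, workflow = name, version = ver$version_string)
}

#' Scheduler status text with known ground truth
#'
#' Emits job-status text in a dialect's long format from an explicit
#' plan, alongside the ground truth the parser must recover — the
#' round-trip that anchors the status-parser tests.
#'
#' @param dialect `"torque"` or `"slurm"`.
#' @param jobs_plan list of `list(id =, name =, state =, exit =)` where
#'   state is one of `queued`, `running`, `held`, `completed`, `exiting`.
#' @param nodes_plan list of `list(name =, cores =, busy =, online =)`.
#' @param disk_available bytes free on the shared filesystem.
#' @return list with `queue_text`, `node_text`, `disk_text`, and
#'   `ground_truth` (tibble of the planned job states).
#' @export
fixture_status_text <- function(dialect = c("torque", "slurm"),
                                jobs_plan = list(), nodes_plan = list(),
                                disk_available = 500 * 1024^3) {
  dialect <- match.arg(dialect)
  queue_text <- paste(vapply(jobs_plan, function(j) {
    if (dialect == "torque") torque_job_block(j) else slurm_job_block(j)
  }, character(1)), collapse = "\n\n")
  node_text <- paste(vapply(nodes_plan, function(nd) {
    if (dialect == "torque") torque_node_block(nd) else slurm_node_block(nd)
  }, character(1)), collapse = "\n\n")
  disk_text <- paste(
    "Filesystem      1B-blocks        Used   Available Use% Mounted on",
    sprintf("/dev/shared  %12.0f %11.0f %11.0f  40%% /share",
            disk_available * 2, disk_available, disk_available),
    sep = "\n")
  gt <- dplyr::bind_rows(lapply(jobs_plan, function(j) {
    tibble(backend_job_id = as.character(j$id), state = j$state,
           exit_status = if (is.null(j$exit)) NA_integer_ else as.integer(j$exit))
  }))
  list(queue_text = queue_text, node_text = node_text,
       disk_text = disk_text, ground_truth = gt)
}

torque_job_block <- function(j) {
  code <- c(queued = "Q", running = "R", held = "H",
            completed = "C", exiting = "E")[[j$state]]
  lines <- c(sprintf("Job Id: %s", j$id),
             sprintf("    Job_Name = %s", j$name %||% "job"),
             sprintf("    job_state = %s", code),
             "    queue = batch",
             "    resources_used.walltime = 00:01:00",
             "    resources_used.mem = 1024kb")
  if (!is.null(j$exit)) {
    lines <- c(lines, sprintf("    exit_status = %d", as.integer(j$exit)))
  }
  paste(lines, collapse = "\n")
}

slurm_job_block <- function(j) {
  st <- c(queued = "PENDING", running = "RUNNING", held = "SUSPENDED",
          completed = "COMPLETED", exiting = "COMPLETING")[[j$state]]
  lines <- c(sprintf("JobId=%s JobName=%s", j$id, j$name %||% "job"),
             sprintf("   JobState=%s Reason=None", st),
             "   RunTime=00:01:00 NumCPUs=1 NumNodes=1")
  if (!is.null(j$exit)) {
    lines <- c(lines, sprintf("   ExitCode=%d:0", as.integer(j$exit)))
  }
  paste(lines, collapse = "\n")
}

torque_node_block <- function(nd) {
  busy <- nd$busy %||% 0
  jobs <- if (busy > 0) {
    paste(sprintf("%d/%d.master", seq_len(busy) - 1, seq_len(busy)), collapse = ", ")
  } else ""
  lines <- c(nd$name,
             sprintf("     state = %s", if (isTRUE(nd$online)) "free" else "down"),
             sprintf("     np = %d", as.integer(nd$cores)))
  if (nzchar(jobs)) lines <- c(lines, sprintf("     jobs = %s", jobs))
  paste(lines, collapse = "\n")
}

slurm_node_block <- function(nd) {
  sprintf("NodeName=%s CPUTot=%d CPUAlloc=%d State=%s",
          nd$name, as.integer(nd$cores), as.integer(nd$busy %||% 0),
          if (isTRUE(nd$online)) "IDLE" else "DOWN")
}

#' Random valid resource requests
#'
#' Draws resource requests across realistic ranges (memory in whole
#' megabytes, as users request it) for round-trip tests of the job-script
#' dialects; the same seed always yields the same sequence.
#'
#' @param n number of requests.
#' @param seed RNG seed.
#' @return list of [resource_request()]s.
#' @export
fixture_resource_requests <- function(n, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      resource_request(
        nodes = sample(1:32, 1),
        cores_per_node = sample(1:64, 1),
        memory = sample(c(256, 512, 1024, 2048, 4096, 8192, 16384, 131072), 1) * 1024^2,
        walltime = sample(c(60, 600, 3600, 86400, 172800), 1) + sample(0:59, 1),
        queue = if (runif(1) < 0.5) sample(c("batch", "long", "gpu"), 1) else NULL)
    })
  })
}
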