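# shared helpers: oracles and shorthand constructors

# independent brute-force oracle for checkpoint eligibility: Floyd-Warshall
# transitive closure, then pairwise comparability
bf_checkpoint_oracle <- function(stage_ids, edges) {
  n <- length(stage_ids)
  reach <- matrix(FALSE, n, n, dimnames = list(stage_ids, stage_ids))
  diag(reach) <- TRUE
  for (e in edges) reach[e$parent, e$child] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  eligible <- vapply(seq_len(n), function(i) {
    all(reach[i, ] | reach[, i])
  }, logical(1))
  sort(stage_ids[eligible])
}

# a throwaway manager over a fresh temp working root
test_manager <- function(registry, ...) {
  job_manager(registry,
              config = stageflow_config(workdir_root = tempfile("sfroot"), ...))
}

# workflow_state from a fixture pattern without registering anything
pattern_state <- function(pattern, ...) {
  pat <- fixture_pattern(pattern, ...)
  workflow_state(
    paste0("pat-", pattern),
    lapply(pat$stage_ids, stage, tool = "step"),
    lapply(pat$edges, function(e) stage_dependency(e$parent, e$child, e$condition, e$code))
  )
}

# states of all stages of a job as a named character vector
stage_states <- function(job) {
  vapply(job$stage_runs, `[[`, character(1), "state")
}

simple_tool <- function(name = "t", ...) {
  tool_definition(name, "echo ${msg}",
                  parameters = list(parameter_spec("msg", default = "hi")), ...)
}
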