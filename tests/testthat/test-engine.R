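finished_run <- function(exit, state = if (!is.null(exit) && exit == 0) "COMPLETED" else "FAILED") {
  r <- stageflow:::new_stage_run("P")
  r$state <- state
  r$exit_status <- exit
  r
}

test_that("conditions fire on the parent's exit status", {
  dep <- function(cond, code = NULL) stage_dependency("P", "C", cond, code)
  expect_true(evaluate_condition(dep("on_exit_code", 1), finished_run(1L)))
  expect_false(evaluate_condition(dep("on_exit_code", 2), finished_run(1L)))
  expect_true(evaluate_condition(dep("on_success"), finished_run(0L)))
  expect_false(evaluate_condition(dep("on_fail"), finished_run(0L)))
  expect_true(evaluate_condition(dep("on_fail"), finished_run(7L)))
  # an exit-code-0 edge is synonymous with on_success
  expect_true(evaluate_condition(dep("on_exit_code", 0), finished_run(0L)))
  # a backend abort (failed, no exit code) counts as failure
  expect_true(evaluate_condition(dep("on_fail"), finished_run(NULL, "FAILED")))
  expect_false(evaluate_condition(dep("on_success"), finished_run(NULL, "FAILED")))
  # unfinished parents are a caller error
  expect_error(evaluate_condition(dep("on_success"),
                                  stageflow:::new_stage_run("P")),
               "has not finished")
})

test_that("ready set: sources first, AND across incoming edges", {
  fx <- fixture_workflow("fig4c", exit_codes = c(D = 5),
                         delays = c(B = 0.4))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, run = FALSE)
  # at the start only the source stage is ready
  expect_identical(ready_stages(job), "A")
  jm$step(job)  # launches A
  expect_identical(stage_states(job)[["A"]], "RUNNING")
  while (stage_states(job)[["A"]] == "RUNNING") { jm$step(job); Sys.sleep(0.01) }
  # after A exits 0, B and C become ready simultaneously (B slept, still running)
  while (stage_states(job)[["C"]] != "COMPLETED") { jm$step(job); Sys.sleep(0.01) }
  # D waits until BOTH B and C finish
  if (stage_states(job)[["B"]] == "RUNNING") {
    expect_identical(ready_stages(job), character())
    expect_identical(stage_states(job)[["D"]], "WAITING")
  }
  jm$run_job(job)
  expect_identical(job$status, "COMPLETED")
  expect_identical(stage_states(job)[["E"]], "COMPLETED")
})

test_that("success/failure fork: exactly one branch runs, the other is skipped", {
  reg <- tool_registry()
  fx <- fixture_workflow("fig4a", registry = reg, name = "fork-ok")
  jm <- test_manager(reg)
  ok <- jm$submit("fork-ok", "1.0.0")
  expect_identical(stage_states(ok)[c("B", "C")],
                   c(B = "COMPLETED", C = "SKIPPED"))
  expect_identical(ok$status, "COMPLETED")

  fixture_workflow("fig4a", exit_codes = c(A = 1), registry = reg, name = "fork-fail")
  failed_parent <- jm$submit("fork-fail", "1.0.0")
  expect_identical(stage_states(failed_parent)[c("B", "C")],
                   c(B = "SKIPPED", C = "COMPLETED"))
  expect_identical(failed_parent$status, "COMPLETED")
})

test_that("exit-code fork completes only for consumed codes", {
  for (code in 0:3) {
    fx <- fixture_workflow("fig4b", exit_codes = c(A = code),
                           name = sprintf("w%d", code))
    job <- test_manager(fx$registry)$submit(sprintf("w%d", code), "1.0.0")
    if (code == 1) {
      expect_identical(stage_states(job)[["B"]], "COMPLETED")
      expect_identical(job$status, "COMPLETED")
    } else if (code == 2) {
      expect_identical(stage_states(job)[["C"]], "COMPLETED")
      expect_identical(job$status, "COMPLETED")
    } else {
      expect_identical(unname(stage_states(job)[c("B", "C")]),
                       c("SKIPPED", "SKIPPED"))
      expect_identical(job$status, "FAILED")
    }
  }
})

test_that("independent stages start together; the join starts after both", {
  fx <- fixture_workflow("fig12_shape", delays = c(s1 = 0.25, s2 = 0.25))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, max_workers = 2)
  expect_identical(job$status, "COMPLETED")
  tb <- tidy(job)
  tb <- tb[order(tb$stage_id), ]
  s1 <- tb[tb$stage_id == "s1", ]; s2 <- tb[tb$stage_id == "s2", ]
  s3 <- tb[tb$stage_id == "s3", ]
  # s1 and s2 overlap in time (ran concurrently under a 2-worker pool)
  expect_lt(as.numeric(s1$started_at), as.numeric(s2$finished_at))
  expect_lt(as.numeric(s2$started_at), as.numeric(s1$finished_at))
  # the join only starts after both end
  expect_gte(as.numeric(s3$started_at),
             max(as.numeric(s1$finished_at), as.numeric(s2$finished_at)))
})

test_that("stage outputs land in the shared working directory with sidecars", {
  fx <- fixture_workflow("linear", n = 2)
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version)
  wd <- job$working_dir
  expect_true(file.exists(file.path(wd, "s01.done")))
  expect_true(file.exists(file.path(wd, "s02.done")))
  for (s in c("s01", "s02")) {
    expect_true(file.exists(file.path(wd, sprintf("stage_%s.out", s))))
    expect_true(file.exists(file.path(wd, sprintf("stage_%s.exit", s))))
  }
  expect_match(job$stage_runs$s01$stdout, "stage s01 ran")
  expect_identical(readLines(file.path(wd, "stage_s01.exit"))[1], "0")
})

test_that("missing required parameters are reported by key", {
  reg <- tool_registry()
  reg$create_tool(tool_definition(
    "needy", "cat ${infile}",
    parameters = list(parameter_spec("infile", kind = "file", required = TRUE))))
  reg$publish_tool("needy", "1.0.0")
  reg$create_workflow(workflow_state("w", list(stage("A", "needy")), list()))
  reg$publish_workflow("w", "1.0.0")
  jm <- test_manager(reg)
  expect_error(jm$submit("w", "1.0.0"), "missing required parameter.*infile")
})

test_that("file parameters are staged into the working directory", {
  src <- tempfile(fileext = ".txt")
  writeLines("payload", src)
  reg <- tool_registry()
  reg$create_tool(tool_definition(
    "cat", "cat ${infile}",
    parameters = list(parameter_spec("infile", kind = "file", required = TRUE))))
  reg$publish_tool("cat", "1.0.0")
  reg$create_workflow(workflow_state("w", list(stage("A", "cat")), list()))
  reg$publish_workflow("w", "1.0.0")
  jm <- test_manager(reg)
  job <- jm$submit("w", "1.0.0", inputs = list(infile = src))
  expect_identical(job$status, "COMPLETED")
  expect_true(file.exists(file.path(job$working_dir, basename(src))))
  expect_match(job$stage_runs$A$stdout, "payload")
})

test_that("input profiles fill gaps and user inputs override them", {
  ps <- list(parameter_spec("p1", required = TRUE), parameter_spec("p2"))
  prof <- input_profile("defaults", "tool:t", list(p1 = "a"))
  expect_identical(apply_input_profile(ps, list(p2 = "b"), prof),
                   list(p1 = "a", p2 = "b"))
  expect_identical(apply_input_profile(ps, list(p1 = "c"), prof), list(p1 = "c"))
  expect_error(apply_input_profile(ps, list(), NULL), "missing required")
  expect_error(apply_input_profile(ps, list(zz = 1), prof), "unknown parameter 'zz'")
  # end to end: profile resolved through the registry by name
  fx <- fixture_workflow("linear", n = 1, user_params = "marker")
  fx$registry$save_profile(input_profile(
    "loud", paste0("workflow:", fx$workflow), list(marker = "custom")))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, profile = "loud")
  expect_true(file.exists(file.path(job$working_dir, "custom.done")))
  # and a user input beats the profile value
  job2 <- jm$submit(fx$workflow, fx$version, profile = "loud",
                    inputs = list(marker = "winner"))
  expect_true(file.exists(file.path(job2$working_dir, "winner.done")))
})

test_that("a profile for a different workflow is refused", {
  fx <- fixture_workflow("linear", n = 1)
  jm <- test_manager(fx$registry)
  wrong <- input_profile("x", "workflow:other", list(marker = "m"))
  expect_error(jm$submit(fx$workflow, fx$version, profile = wrong), "targets")
})

test_that("batch submission yields one job per row, in row order", {
  fx <- fixture_workflow("linear", n = 1, user_params = c("marker", "code"))
  jm <- test_manager(fx$registry)
  batch <- "marker\tcode\nrow1\t0\nrow2\t0\nrow3\t0"
  jobs <- jm$submit_batch(fx$workflow, fx$version, batch)
  expect_length(jobs, 3)
  markers <- vapply(jobs, function(j) j$stage_runs$s01$resolved_parameters$marker,
                    character(1))
  expect_identical(markers, c("row1", "row2", "row3"))
  expect_true(all(vapply(jobs, function(j) j$status, character(1)) == "COMPLETED"))
  # header-only file: no jobs
  expect_length(jm$submit_batch(fx$workflow, fx$version, "marker"), 0)
  # arity mismatch names the 1-based row
  expect_error(parse_batch_file("a,b,c\n1,2"), "row 1: expected 3 fields")
  # comma dialect auto-detected
  expect_identical(parse_batch_file("a,b\n1,2")$b, "2")
  # unknown header key surfaces at submission
  expect_error(jm$submit_batch(fx$workflow, fx$version, "nosuch\nx"),
               "unknown parameter")
})

test_that("cancel stops running stages and prevents new launches", {
  fx <- fixture_workflow("linear", n = 3, delays = c(s01 = 2))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, run = FALSE)
  jm$step(job)
  expect_identical(stage_states(job)[["s01"]], "RUNNING")
  jm$control(job$job_id, "cancel")
  expect_identical(job$status, "CANCELLED")
  expect_identical(unname(stage_states(job)), rep("CANCELLED", 3))
  expect_null(job$stage_runs$s01$exit_status)
  # no exit sidecar was written for the killed stage
  expect_false(file.exists(file.path(job$working_dir, "stage_s01.exit")))
})

test_that("hold pauses scheduling and release resumes it", {
  fx <- fixture_workflow("linear", n = 2)
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, run = FALSE)
  jm$control(job$job_id, "hold")
  expect_identical(job$status, "HELD")
  jm$step(job)
  expect_identical(stage_states(job)[["s01"]], "WAITING")  # nothing launched
  expect_error(jm$control(job$job_id, "hold"), "cannot hold")
  jm$control(job$job_id, "release")
  expect_identical(job$status, "COMPLETED")
  expect_error(jm$control(job$job_id, "release"), "not held")
})

test_that("delete removes the history record; files persist unless purged", {
  fx <- fixture_workflow("linear", n = 1)
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version)
  wd <- job$working_dir
  expect_true(jm$history$has_job(job$job_id))
  jm$control(job$job_id, "delete")
  expect_false(jm$history$has_job(job$job_id))
  expect_true(dir.exists(wd))  # retention default: files stay

  job2 <- jm$submit(fx$workflow, fx$version)
  wd2 <- job2$working_dir
  jm$control(job2$job_id, "delete", purge = TRUE)
  expect_false(dir.exists(wd2))
  # active jobs cannot be deleted; strangers cannot control jobs
  job3 <- jm$submit(fx$workflow, fx$version, run = FALSE)
  expect_error(jm$control(job3$job_id, "delete"), "active")
  expect_error(jm$control(job3$job_id, "cancel", user = "eve"), "may not")
  jm$run_job(job3)
})

test_that("terminal stage states are exclusive and conserved", {
  outcomes <- list(
    fixture_workflow("fig4a", exit_codes = c(A = 1), name = "t1"),
    fixture_workflow("fig4b", exit_codes = c(A = 3), name = "t2"),
    fixture_workflow("fig4c", exit_codes = c(D = 5), name = "t3"))
  for (fx in outcomes) {
    job <- test_manager(fx$registry)$submit(fx$workflow, "1.0.0")
    states <- stage_states(job)
    expect_identical(length(states), length(job$stages_by_id))
    expect_true(all(states %in% c("COMPLETED", "FAILED", "SKIPPED", "CANCELLED")))
  }
})

test_that("outcome is deterministic across scheduling perturbations", {
  fx <- fixture_workflow("fig4c", exit_codes = c(D = 5))
  jm <- test_manager(fx$registry)
  reference <- NULL
  for (i in 1:10) {
    job <- jm$submit(fx$workflow, fx$version,
                     jitter = function() runif(1, 0, 0.02))
    key <- paste(stage_states(job), collapse = "|")
    sig <- paste(job$status, key)
    if (is.null(reference)) reference <- sig
    expect_identical(sig, reference)
  }
})
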