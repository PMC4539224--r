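terminal_stage <- function(id = "A", state = "COMPLETED", exit = 0L) {
  r <- stageflow:::new_stage_run(id, list(p = "v"))
  r$state <- state
  r$exit_status <- if (state %in% c("COMPLETED", "FAILED")) exit else NULL
  r$stdout <- "out"; r$stderr <- ""
  r$started_at <- Sys.time(); r$finished_at <- Sys.time()
  r
}

fake_job <- function(id, user = "ann", workflow = "w") {
  j <- JobRun$new()
  j$job_id <- id; j$user <- user; j$workflow <- workflow; j$version <- "1.0.0"
  j$created_at <- Sys.time(); j$working_dir <- tempfile()
  j
}

test_that("stage records store and fetch field-equal, idempotently", {
  hs <- history_store()
  hs$create_job(fake_job("j1"))
  hs$record_stage("j1", terminal_stage("A"))
  rec <- hs$get_job("j1")
  expect_identical(rec$stages$A$state, "COMPLETED")
  expect_identical(rec$stages$A$exit_status, 0L)
  expect_identical(rec$stages$A$resolved_parameters$p, "v")
  expect_identical(rec$stages$A$stdout, "out")
  # idempotent re-store of the same terminal state: still one entry
  hs$record_stage("j1", terminal_stage("A"))
  expect_length(hs$get_job("j1")$stages, 1)
  # non-terminal stages are refused; unknown jobs are an error
  expect_error(hs$record_stage("j1", stageflow:::new_stage_run("B")), "not terminal")
  expect_error(hs$record_stage("ghost", terminal_stage("A")), "no history record")
  hs$delete_job("j1")
  expect_error(hs$record_stage("j1", terminal_stage("A")), "no history record")
})

test_that("sharing grants read access but not control", {
  fx <- fixture_workflow("linear", n = 1)
  jm <- test_manager(fx$registry)
  reg <- fx$registry
  reg$set_public("workflow", fx$workflow, TRUE)
  job <- jm$submit(fx$workflow, fx$version, user = "ann")
  hs <- jm$history
  # unshared: another user cannot read
  expect_error(hs$get_job(job$job_id, user = "bea"), "may not read")
  expect_error(hs$share_job(job$job_id, "bea", "bea"), "does not own")
  hs$share_job(job$job_id, "ann", "bea")
  rec <- hs$get_job(job$job_id, user = "bea")
  expect_match(rec$stages$s01$stdout, "stage s01 ran")
  # recipients cannot delete or cancel
  expect_error(jm$control(job$job_id, "delete", user = "bea"), "may not")
  expect_true(hs$has_job(job$job_id))
})

test_that("history queries filter conjunctively, newest first", {
  hs <- history_store()
  for (i in 1:3) {
    j <- fake_job(sprintf("j%d", i), user = if (i == 2) "bea" else "ann",
                  workflow = if (i == 3) "other" else "w")
    j$created_at <- as.POSIXct("2026-01-01", tz = "UTC") + i * 3600
    hs$create_job(j)
    j$status <- if (i == 1) "FAILED" else "COMPLETED"
    j$finished_at <- j$created_at + 60
    hs$finalize_job(j)
  }
  all <- hs$query()
  expect_identical(all$job_id, c("j3", "j2", "j1"))  # newest first
  expect_identical(hs$query(status = "FAILED")$job_id, "j1")
  expect_identical(hs$query(user = "ann", workflow = "w")$job_id, c("j1"))
  expect_identical(nrow(hs$query(from = "2026-02-01")), 0L)
  expect_identical(nrow(hs$query(to = "2026-01-01T01:30:00")), 1L)
  # visibility restriction: own jobs only unless shared
  expect_identical(hs$query(as_user = "bea")$job_id, "j2")
  hs$share_job("j1", "ann", "bea")
  expect_identical(sort(hs$query(as_user = "bea")$job_id), c("j1", "j2"))
})

test_that("every engine run leaves a complete history record", {
  fx <- fixture_workflow("fig4c", exit_codes = c(D = 5), checkpoints = "D")
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version)
  rec <- jm$history$get_job(job$job_id)
  expect_identical(rec$status, "COMPLETED")
  expect_length(rec$stages, 5)
  for (s in rec$stages) {
    expect_true(s$state %in% c("COMPLETED", "FAILED", "SKIPPED", "CANCELLED"))
    if (s$state %in% c("COMPLETED", "FAILED")) {
      expect_false(is.null(s$exit_status))
      expect_false(is.null(s$stdout))
      expect_false(is.null(s$stderr))
      expect_true(length(s$resolved_parameters) > 0)
    }
  }
  # sequential stages carry post-stage snapshot refs when the switch is on
  expect_identical(rec$stages$A$post_snapshot_ref, "after-A")
  expect_identical(rec$stages$D$snapshot_ref, "checkpoint-D")
  # failed jobs are recorded too
  fx2 <- fixture_workflow("fig4b", exit_codes = c(A = 3))
  jm2 <- test_manager(fx2$registry)
  job2 <- jm2$submit(fx2$workflow, "1.0.0")
  expect_identical(jm2$history$get_job(job2$job_id)$status, "FAILED")
})

test_that("poll ticks refresh active jobs and survive a dead backend", {
  fx <- fixture_workflow("linear", n = 2, delays = c(s01 = 0.2))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, run = FALSE)
  expect_identical(poll_tick(jm)$status, "RUNNING")
  while (job$status %in% c("QUEUED", "RUNNING")) { poll_tick(jm); Sys.sleep(0.02) }
  expect_identical(job$status, "COMPLETED")
  expect_identical(nrow(poll_tick(jm)), 0L)  # no active jobs left

  # a backend outage leaves records untouched and warns
  fx2 <- fixture_workflow("linear", n = 1, delays = c(s01 = 1), registry = fx$registry,
                          name = "w2")
  jm2 <- test_manager(fx2$registry)
  job2 <- jm2$submit("w2", "1.0.0", run = FALSE)
  jm2$step(job2)
  down <- R6::R6Class("Down", inherit = ResourceBackend, public = list(
    name = "down",
    status = function(id) rlang::abort("scheduler offline", class = "backend_unavailable")
  ))$new()
  real <- jm2$backend
  jm2$backend <- down
  expect_warning(poll_tick(jm2), "backend unavailable")
  expect_identical(stage_states(job2)[["s01"]], "RUNNING")  # untouched
  jm2$backend <- real
  jm2$run_job(job2)
  expect_identical(job2$status, "COMPLETED")
})

test_that("rerun from history reproduces the recorded resolved parameters", {
  fx <- fixture_workflow("linear", n = 2, checkpoints = "s01",
                         user_params = "marker")
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, inputs = list(`s01.marker` = "m1"))
  resumed <- jm$resume(job$job_id, "s01")
  orig <- jm$history$get_job(job$job_id)
  rerun <- jm$history$get_job(resumed$job_id)
  for (sid in names(orig$stages)) {
    expect_identical(rerun$stages[[sid]]$resolved_parameters,
                     orig$stages[[sid]]$resolved_parameters)
  }
})
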