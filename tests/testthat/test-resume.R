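test_that("checkpoint stages snapshot the working directory at stage start", {
  fx <- fixture_workflow("linear", n = 3, checkpoints = "s02")
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version)
  sr <- job$stage_runs$s02
  expect_identical(sr$snapshot_ref, "checkpoint-s02")
  snap <- file.path(job$working_dir, ".snapshots", sr$snapshot_ref)
  # the snapshot holds stage 1's output but not stage 2's or 3's
  expect_true(file.exists(file.path(snap, "s01.done")))
  expect_false(file.exists(file.path(snap, "s02.done")))
  # non-checkpoint stages carry no start snapshot
  expect_null(job$stage_runs$s01$snapshot_ref)
})

test_that("snapshot restore reproduces the identical content digest", {
  d <- tempfile(); dir.create(file.path(d, "sub"), recursive = TRUE)
  writeLines("alpha", file.path(d, "a.txt"))
  writeLines("beta", file.path(d, "sub", "b.txt"))
  before <- workdir_digest(d)
  take_snapshot(d, "s1")
  expect_identical(snapshot_digest(d, "s1"), before)
  # mutate, then restore
  writeLines("gamma", file.path(d, "a.txt"))
  writeLines("new", file.path(d, "c.txt"))
  expect_false(workdir_digest(d) == before)
  restore_snapshot(d, "s1")
  expect_identical(workdir_digest(d), before)
  # idempotence: restore then snapshot again gives the same archive digest
  take_snapshot(d, "s2")
  expect_identical(snapshot_digest(d, "s2"), snapshot_digest(d, "s1"))
})

test_that("resume after an interruption reproduces the uninterrupted run", {
  build <- function(name) {
    fixture_workflow("linear", n = 4, checkpoints = c("s02", "s03"),
                     delays = c(s03 = 0.5),
                     registry = tool_registry(), name = name)
  }
  # reference: uninterrupted run
  fx1 <- build("chain")
  jm1 <- test_manager(fx1$registry)
  full <- jm1$submit("chain", "1.0.0")
  expect_identical(full$status, "COMPLETED")
  reference_digest <- workdir_digest(full$working_dir)

  # interrupted run: cancel while stage 3 is executing, then resume at s03
  fx2 <- build("chain")
  jm2 <- test_manager(fx2$registry)
  interrupted <- jm2$submit("chain", "1.0.0", run = FALSE)
  while (stage_states(interrupted)[["s03"]] != "RUNNING") {
    jm2$step(interrupted); Sys.sleep(0.01)
  }
  jm2$control(interrupted$job_id, "cancel")
  expect_identical(interrupted$status, "CANCELLED")

  resumed <- jm2$resume(interrupted$job_id, "s03")
  expect_identical(resumed$status, "COMPLETED")
  # stages before the checkpoint carried over, not re-run
  expect_true(resumed$stage_runs$s01$carried)
  expect_true(resumed$stage_runs$s02$carried)
  expect_false(resumed$stage_runs$s03$carried)
  expect_false(identical(resumed$working_dir, interrupted$working_dir))
  expect_identical(workdir_digest(resumed$working_dir), reference_digest)
})

test_that("resume from the first stage re-runs everything with recorded inputs", {
  fx <- fixture_workflow("linear", n = 3, checkpoints = "s01",
                         user_params = "marker")
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, inputs = list(`s02.marker` = "custom"))
  resumed <- jm$resume(job$job_id, "s01")
  expect_identical(resumed$status, "COMPLETED")
  expect_true(all(!vapply(resumed$stage_runs, `[[`, logical(1), "carried")))
  # recorded parameters reused verbatim
  expect_identical(resumed$stage_runs$s02$resolved_parameters$marker, "custom")
  expect_true(file.exists(file.path(resumed$working_dir, "custom.done")))
  expect_identical(workdir_digest(resumed$working_dir),
                   workdir_digest(job$working_dir))
})

test_that("resume refuses non-checkpoints, unknown stages and active jobs", {
  fx <- fixture_workflow("linear", n = 3, checkpoints = "s02",
                         delays = c(s01 = 2))
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version, run = FALSE)
  jm$step(job)
  expect_error(jm$resume(job$job_id, "s02"), "still active")
  jm$control(job$job_id, "cancel")
  expect_error(jm$resume(job$job_id, "s01"), "not a checkpoint")
  expect_error(jm$resume(job$job_id, "zz"), "no stage")
  # a checkpoint that was never reached has no snapshot to restore
  expect_error(jm$resume(job$job_id, "s02"), "not a checkpoint with a snapshot")
})

test_that("no stage runs twice within one job; resume creates a new record", {
  fx <- fixture_workflow("linear", n = 2, checkpoints = "s02")
  jm <- test_manager(fx$registry)
  job <- jm$submit(fx$workflow, fx$version)
  resumed <- jm$resume(job$job_id, "s02")
  expect_false(identical(job$job_id, resumed$job_id))
  expect_identical(resumed$resumed_from, job$job_id)
  # original record untouched
  expect_identical(job$stage_runs$s02$state, "COMPLETED")
  expect_true(jm$history$has_job(job$job_id) && jm$history$has_job(resumed$job_id))
})
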