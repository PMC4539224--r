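test_that("the local backend runs scripts, captures streams and exit codes", {
  b <- local_backend()
  d <- tempfile(); dir.create(d)
  id <- b$submit("echo out; echo err >&2; exit 5", d, tag = "stage_A")
  while (b$status(id)$state %in% c("queued", "running")) Sys.sleep(0.01)
  st <- b$status(id)
  expect_identical(st$state, "completed")
  expect_identical(st$exit_status, 5L)
  expect_identical(readLines(file.path(d, "stage_A.out"))[1], "out")
  expect_identical(readLines(file.path(d, "stage_A.err"))[1], "err")
  expect_identical(readLines(file.path(d, "stage_A.exit"))[1], "5")
  # files written by the script land in the working directory
  id2 <- b$submit("echo data > artifact.txt", d, tag = "stage_B")
  while (b$status(id2)$state != "completed") Sys.sleep(0.01)
  expect_true(file.exists(file.path(d, "artifact.txt")))
  expect_error(b$submit("exit 0", file.path(d, "nope")), "does not exist")
  expect_error(b$status("local-999999"), "unknown backend job")
})

test_that("cancelling a local job kills it and leaves no exit sidecar", {
  b <- local_backend()
  d <- tempfile(); dir.create(d)
  id <- b$submit("sleep 5; exit 0", d, tag = "stage_S")
  Sys.sleep(0.1)
  expect_identical(b$status(id)$state, "running")
  b$cancel(id)
  Sys.sleep(0.05)
  expect_identical(b$status(id)$state, "cancelled")
  expect_false(file.exists(file.path(d, "stage_S.exit")))
})

test_that("job scripts round-trip resource requests in both dialects", {
  reqs <- fixture_resource_requests(100, seed = 7)
  for (dialect in c("torque", "slurm")) {
    for (r in reqs) {
      script <- generate_job_script("echo run", r, dialect, name = "rt")
      back <- parse_job_script(script, dialect)
      expect_identical(back$nodes, r$nodes)
      expect_identical(back$cores_per_node, r$cores_per_node)
      expect_identical(back$memory, r$memory)
      expect_identical(back$walltime, r$walltime)
      expect_identical(back$queue, r$queue)
    }
  }
})

test_that("generated scripts carry the dialect's directives and the exit wrapper", {
  r <- resource_request(1, 2, 4 * 1024^3, 3600, queue = "batch")
  tq <- generate_job_script("prog --x", r, "torque", name = "myjob",
                            stdout_path = "o.txt", stderr_path = "e.txt",
                            exit_path = "stage.exit")
  expect_match(tq, "^#!/bin/sh")
  expect_match(tq, "#PBS -N myjob", fixed = TRUE)
  expect_match(tq, "#PBS -l nodes=1:ppn=2", fixed = TRUE)
  expect_match(tq, "#PBS -l mem=4096mb", fixed = TRUE)
  expect_match(tq, "#PBS -l walltime=01:00:00", fixed = TRUE)
  expect_match(tq, "#PBS -q batch", fixed = TRUE)
  expect_match(tq, "echo $? > stage.exit", fixed = TRUE)
  sl <- generate_job_script("prog --x", r, "slurm")
  expect_match(sl, "#SBATCH --nodes=1", fixed = TRUE)
  expect_match(sl, "#SBATCH --ntasks-per-node=2", fixed = TRUE)
  expect_match(sl, "#SBATCH --mem=4096", fixed = TRUE)
  expect_match(sl, "#SBATCH --time=01:00:00", fixed = TRUE)
  expect_match(sl, "#SBATCH --partition=batch", fixed = TRUE)
  expect_error(generate_job_script("x", r, "uge"), "arg")
  expect_error(parse_job_script("#!/bin/sh\necho x", "torque"), "nodes/ppn")
})

test_that("unimplemented plugin operations raise the uniform signal", {
  uge <- UgeBackend$new()
  for (call in list(
    function() uge$submit("x", tempdir()),
    function() uge$status("1"),
    function() uge$cancel("1"),
    function() uge$cluster_snapshot())) {
    expect_error(call(), "not supported by plugin", class = "backend_not_supported")
  }
})

test_that("a plugin dropped into the plugin directory loads by name alone", {
  plugdir <- tempfile(); dir.create(plugdir)
  writeLines(c(
    "backend_toy <- function() {",
    "  b <- local_backend()",
    "  b$name <- 'toy'",
    "  b",
    "}"), file.path(plugdir, "toy.R"))
  cfg <- stageflow_config(plugin_dir = plugdir)
  b <- load_backend("toy", cfg)
  expect_s3_class(b, "ResourceBackend")
  expect_identical(b$name, "toy")
  expect_error(load_backend("ghost", cfg), "no plugin file")
  # built-ins resolve without a plugin directory
  expect_identical(load_backend("local")$name, "local")
  expect_identical(load_backend("torque")$name, "torque")
  expect_identical(load_backend("slurm")$name, "slurm")
})

test_that("scheduler backends report unavailability when commands are missing", {
  # no Torque is installed on the test machine, and the engine must say so
  b <- scheduler_backend("torque")
  d <- tempfile(); dir.create(d)
  expect_error(b$submit("#!/bin/sh\nexit 0", d), class = "backend_unavailable")
})

test_that("typed data objects require covering metadata and known kinds", {
  expect_error(typed_data_object(list(a = 1), list()), "metadata missing")
  expect_error(
    typed_data_object(list(a = 1), list(a = list(label = "A", value_kind = "weird"))),
    "unknown value kind")
  tdo <- typed_data_object(
    list(mem = 1024, state = "R"),
    list(mem = list(label = "Memory", value_kind = "bytes"),
         state = list(label = "State", value_kind = "state")),
    source = "torque")
  tb <- tidy(tdo)
  expect_identical(tb$value_kind, c("bytes", "state"))
  expect_identical(unique(tb$source), "torque")
})

test_that("configuration reads YAML and applies overrides", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("backend: slurm", "poll_interval: 2", "max_workers: 4"), f)
  cfg <- stageflow_config(f, poll_interval = 1)
  expect_identical(cfg$backend, "slurm")
  expect_identical(cfg$poll_interval, 1)
  expect_identical(cfg$max_workers, 4L)
  expect_identical(stageflow_config()$backend, "local")
})
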