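test_that("canonical serialization is order- and newline-invariant", {
  a <- list(b = 1, a = list(y = "x\r\nz", x = 2))
  b <- list(a = list(x = 2, y = "x\nz"), b = 1)
  expect_identical(as.character(canonical_json(a)), as.character(canonical_json(b)))
  expect_identical(content_hash(a), content_hash(b))
  expect_false(content_hash(a) == content_hash(list(b = 2, a = list(y = "x\nz", x = 2))))
})

test_that("parameter specs enforce kinds, choices and defaults", {
  expect_error(parameter_spec("2bad"), "invalid parameter key")
  expect_error(parameter_spec("c", kind = "choice"), "at least one choice")
  expect_error(parameter_spec("c", kind = "choice", choices = c("x", "y"), default = "z"),
               "does not satisfy kind")
  p <- parameter_spec("c", kind = "choice", choices = c("x", "y"), default = "x")
  expect_identical(p$default, "x")
  expect_error(parameter_spec("n", kind = "number", default = "abc"), "does not satisfy")
  expect_error(parameter_spec("t", choices = "x"), "only valid for kind")
})

test_that("resource requests reject non-positive counts and durations", {
  expect_error(resource_request(nodes = 0), "positive")
  expect_error(resource_request(cores_per_node = 0), "positive")
  expect_error(resource_request(memory = 0), "memory")
  expect_error(resource_request(walltime = 0), "walltime")
  r <- resource_request(2, 8, 1024^3, 7200, queue = "batch")
  expect_identical(r$nodes, 2L)
  expect_identical(r$queue, "batch")
})

test_that("command templates bind placeholders to parameters exactly", {
  expect_identical(template_placeholders("p ${a} ${b} ${a}"), c("a", "b"))
  expect_error(
    tool_definition("t", "prog ${missing}"),
    "matches no parameter")
  # ${SCRIPTS} is reserved for the engine, not a parameter
  expect_s3_class(tool_definition("t", "sh ${SCRIPTS}/x.sh"), "tool_definition")
  expect_identical(resolve_command("p ${a}", list(a = "v")), "p v")
  expect_error(resolve_command("p ${a}", list()), "unresolved placeholder")
  expect_identical(resolve_command("p ${f}", list(f = TRUE)), "p 1")
})

test_that("script paths are confined to the tool subtree", {
  expect_error(tool_definition("t", "x", scripts = c("../escape.sh" = "")),
               "not a normalized relative path")
  expect_error(tool_definition("t", "x", scripts = c("/abs.sh" = "")),
               "not a normalized relative path")
  expect_error(tool_definition("t", "x", scripts = c("a//b.sh" = "")),
               "not a normalized relative path")
  ok <- tool_definition("t", "x", scripts = c("sub/dir/run.sh" = "#!/bin/sh\n"))
  expect_named(ok$scripts, "sub/dir/run.sh")
})

test_that("workflow validation reports violations instead of throwing", {
  # the diamond-with-tail pattern is valid
  expect_identical(nrow(validate_workflow(pattern_state("fig4c"))), 0L)

  self_dep <- workflow_state("w", list(stage("A", "t")), list())
  self_dep$dependencies <- list(structure(
    list(parent = "A", child = "A", condition = "on_success", code = NULL),
    class = "stage_dependency"))
  v <- validate_workflow(self_dep)
  expect_true(any(grepl("self-dependency", v$problem)))

  cyc <- workflow_state("w", list(stage("A", "t"), stage("B", "t")),
                        list(stage_dependency("A", "B"), stage_dependency("B", "A")))
  v <- validate_workflow(cyc)
  expect_true(any(grepl("cycle", v$problem)))

  dangling <- workflow_state("w", list(stage("A", "t")),
                             list(stage_dependency("A", "Z")))
  expect_true(any(grepl("unknown child", validate_workflow(dangling)$problem)))

  # bindings checked against the registry's parameter keys
  reg <- tool_registry()
  reg$create_tool(simple_tool("t"))
  bad_binding <- workflow_state("w", list(stage("A", "t", bindings = list(nope = 1))), list())
  expect_true(any(grepl("unknown parameter 'nope'",
                        validate_workflow(bad_binding, reg)$problem)))
})

test_that("checkpoint eligibility is graph comparability", {
  # diamond with tail: B and C are incomparable to each other
  expect_identical(checkpoint_eligible_stages(pattern_state("fig4c")),
                   c("A", "D", "E"))
  # a single stage is trivially eligible
  one <- workflow_state("w", list(stage("A", "t")), list())
  expect_identical(checkpoint_eligible_stages(one), "A")
  # two disconnected stages run in parallel: neither is eligible
  two <- workflow_state("w", list(stage("A", "t"), stage("B", "t")), list())
  expect_identical(checkpoint_eligible_stages(two), character())
  # in a linear chain every stage is eligible
  expect_identical(checkpoint_eligible_stages(pattern_state("linear", n = 5)),
                   sort(sprintf("s%02d", 1:5)))
  # cyclic graphs are rejected
  cyc <- workflow_state("w", list(stage("A", "t"), stage("B", "t")),
                        list(stage_dependency("A", "B"), stage_dependency("B", "A")))
  expect_error(checkpoint_eligible_stages(cyc), "cyclic")
})

test_that("eligibility matches the brute-force comparability oracle on random DAGs", {
  for (i in 1:30) {
    pat <- fixture_pattern("random_dag", n = sample(2:10, 1), edge_p = runif(1, 0.1, 0.6),
                           seed = i)
    st <- workflow_state(
      "w", lapply(pat$stage_ids, stage, tool = "t"),
      lapply(pat$edges, function(e) stage_dependency(e$parent, e$child)))
    expect_identical(checkpoint_eligible_stages(st),
                     bf_checkpoint_oracle(pat$stage_ids, pat$edges),
                     info = sprintf("random DAG seed %d", i))
  }
})

test_that("user_input markers survive the canonical round trip", {
  st <- workflow_state("w", list(stage("A", "t", bindings = list(msg = user_input()))),
                       list())
  content <- stageflow:::workflow_canonical(st)
  back <- stageflow:::workflow_from_canonical(content)
  expect_true(stageflow:::is_user_input(back$stages[[1]]$bindings$msg))
  expect_identical(content_hash(stageflow:::workflow_canonical(back)),
                   content_hash(content))
})
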