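# stageflow

Workflow management for HPC clusters, as an R library: an
immutable-versioned registry of command-line tools and workflows, a DAG
execution engine whose stage dependencies are **conditional on exit
status**, checkpoint/resume via working-directory snapshots, input
profiles and batch submission, a persistent job history with sharing,
and a pluggable resource-manager backend layer (local subprocess
executor for development and testing; Torque and SLURM job-script
dialects and status parsers for clusters).

It is aimed at groups who run multi-stage computational pipelines —
bioinformatics being the motivating case — on a shared cluster, and who
need the infrastructure around those pipelines: reproducible tool
versions, a record of every run, and the ability to resume a long job
from the point where it stopped.

## The model in brief

A workflow is a DAG of stages; each stage invokes a registered tool.  An
edge `parent -> child` carries one of three conditions on the parent's
exit status `s`:

* `on_success` — traversed iff `s = 0`,
* `on_fail` — traversed iff `s ≠ 0` (or the backend aborted the stage),
* `on_exit_code(k)` — traversed iff `s = k`.

A waiting stage becomes ready when **all** of its incoming edges are
satisfied (AND semantics); ready stages run concurrently up to a worker
limit.  A job fails when a finished stage's outgoing conditions match no
edge, or when a stage failure is consumed by no `on_fail`/`on_exit_code`
edge; unreachable stages are skipped transitively.  Because scripts can
choose their own exit codes, this one primitive expresses arbitrary
branching.

A stage may be flagged as a **checkpoint** iff it is comparable to every
other stage in the reachability order of the DAG (all forks have
converged there).  At a checkpoint's start the working directory is
snapshotted; resuming restores the snapshot into a fresh working
directory and re-executes from the checkpoint with the recorded
parameters.

Published tool/workflow versions are deep snapshots identified by a
SHA-256 hash of a canonical serialization; they can never be edited, and
workflow versions pin concrete tool versions.

## A worked example

The classic diamond-with-tail pattern: `A -> {B, C} -> D`, and `E` runs
only if `D` exits with code 5.

```r
library(stageflow)

reg <- tool_registry()
fx  <- fixture_workflow("fig4c", exit_codes = c(D = 5),
                        checkpoints = "D", registry = reg, user = "ann")

jm  <- job_manager(reg, config = stageflow_config(workdir_root = tempfile()))
job <- jm$submit(fx$workflow, fx$version, user = "ann")
job
#> <JobRun job-000001> fixture-fig4c@1.0.0 by ann: COMPLETED
#>   A          COMPLETED  exit=0
#>   B          COMPLETED  exit=0
#>   C          COMPLETED  exit=0
#>   D          FAILED     exit=5
#>   E          COMPLETED  exit=0
```

`B` and `C` ran in parallel after `A`; `D` waited for both; `D`'s exit
code 5 is nonzero (hence stage state `FAILED`) but it is consumed by the
`on_exit_code(5)` edge, so `E` ran and the job **completed**.  Summaries
and history are tibbles:

```r
glance(job)
#> # A tibble: 1 × 11
#>   job_id   workflow version user  status n_stages n_completed n_failed n_skipped
#>   <chr>    <chr>    <chr>   <chr> <chr>     <int>       <int>    <int>     <int>
#> 1 job-000… fixture… 1.0.0   ann   COMPL…        5           4        1         0

jm$history$query()
#> # A tibble: 1 × 8
#>   job_id     workflow      version user  status  created_at finished_at n_stages
#>   <chr>      <chr>         <chr>   <chr> <chr>   <chr>      <chr>          <int>
#> 1 job-000001 fixture-fig4c 1.0.0   ann   COMPLE… 2026-09-2… 2026-09-27…        5
```

`D` was a checkpoint, so the run can be repeated from there with
`jm$resume(job$job_id, "D")`; `tidy(job)` gives the per-stage table and
`ggplot2::autoplot(job)` a stage timeline.

Job scripts for a cluster come from the same resource requests:

```r
cat(generate_job_script("sh run.sh sample.fq",
                        resource_request(1, 8, 16 * 1024^3, 7200, queue = "batch"),
                        "slurm", name = "align"))
#> #!/bin/sh
#> #SBATCH --job-name=align
#> #SBATCH --nodes=1
#> #SBATCH --ntasks-per-node=8
#> #SBATCH --mem=16384
#> #SBATCH --time=02:00:00
#> #SBATCH --partition=batch
#>
#> sh run.sh sample.fq
```

A thin command-line wrapper lives at `inst/cli/stageflow.R`
(`fixtures build`, `run`, `script`, `parse-status`).

## Package layout

| where | what |
|---|---|
| `R/registry.R`, `R/tool.R`, `R/workflow.R` | tool/workflow model, validation, versioning, permissions |
| `R/engine.R`, `R/snapshot.R` | scheduling, conditions, checkpoints, resume, batch |
| `R/backends.R`, `R/dialects.R`, `R/status.R` | backend contract, local executor, Torque/SLURM scripts and parsers |
| `R/history.R` | persistent job records, sharing, queries, poll ticks |
| `R/impersonation.R` | credential envelopes, pluggable authenticator, executor |
| `R/fixtures.R` | deterministic generators for every test input |

See `vignettes/stageflow-methods.Rmd` for the full account of the model,
its assumptions and its limitations.
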