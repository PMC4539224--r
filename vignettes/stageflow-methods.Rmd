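---
title: "How stageflow schedules, checkpoints and versions workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How stageflow schedules, checkpoints and versions workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageflow)
```

stageflow is the library core of a workflow management system for HPC
clusters: a registry of command-line tools with immutable published
versions, workflows that arrange those tools into a DAG whose edges are
conditional on exit status, an execution engine with checkpoint/resume,
and a plugin layer toward resource managers (Torque, SLURM).  This
vignette explains the model, the choices behind it, and what the test
suite does and does not demonstrate.

## The workflow model

A **tool** is any program or script runnable from a terminal.  Its
definition carries a command template with `${key}` placeholders, an
ordered list of parameter specifications (text, number, file, choice,
flag), a resource request (nodes, cores per node, memory in bytes,
walltime in seconds, optional queue), expected output patterns, and any
script files.  Script paths are validated to stay inside the tool's own
subtree, since they are materialized into working directories at run
time.

A **workflow** is a set of stages — each a tool invocation with
parameter bindings — connected by conditional dependencies.  Three edge
conditions exist:

* `on_success`: the parent exited 0,
* `on_fail`: the parent exited nonzero or was aborted by the backend,
* `on_exit_code(k)`: the parent exited exactly `k`.

Exit codes are the branching primitive: a script that chooses its own
exit status steers the run down the matching edge, which is enough to
express arbitrary decision logic.  When a stage has several incoming
edges, **all** of them must be satisfied (AND semantics) — that is what
makes "D runs after B and C both succeed" the natural reading of a
diamond graph.  OR semantics are expressible by duplicating a stage with
one incoming edge each; the engine deliberately does not add a second
edge-combination mode.

"Success" is defined as exit status 0 throughout, and an
`on_exit_code(0)` edge is treated as synonymous with `on_success`.

### Failure and skip propagation

After every stage finishes, two rules run:

1. if the stage has outgoing edges and none of their conditions matched,
   the job fails — the run has reached a fork with no matching branch;
2. if the stage itself failed and no `on_fail` or matching
   `on_exit_code` edge consumes that failure, the job fails.  For a
   terminal stage this means any unconsumed nonzero exit fails the job.

Independently, any waiting stage with at least one permanently
unsatisfiable incoming edge is marked `SKIPPED`, transitively.  A
cancelled parent triggers nothing: cancellation has no exit status, so
neither `on_success` nor `on_fail` edges fire and the descendants are
skipped.  When a failure rule has fired the engine stops launching new
stages, lets running ones finish, marks the remainder skipped and
records the job as `FAILED`.

## Checkpoints and resume

A job can only be resumed from a point where all forks of the workflow
have converged.  A directory snapshot taken at the start of a stage that
runs in parallel with a sibling would capture the sibling mid-flight, so
eligibility is defined **structurally**: a stage is checkpoint-eligible
iff it is comparable (in reachability order, either direction) to every
other stage of the DAG.  Edge conditions are ignored — two conditional
branches that can never co-run at runtime still disqualify each other.
This is the conservative reading, chosen because eligibility then
depends on the graph alone and can be checked at workflow-creation time;
the engine result is property-tested against a brute-force
transitive-closure oracle on random DAGs.

Checkpoint stages snapshot the working directory at stage **start**:
that copy is exactly the state needed to repeat the stage.
Additionally, when `snapshot_sequential` is on (the default), a snapshot
is taken after every sequential (checkpoint-eligible) stage for the job
history; the switch exists to bound disk use for snapshot-heavy
pipelines.  Resuming restores the checkpoint's start snapshot into a
fresh working directory (each run owns exactly one working directory),
carries over the recorded results of every stage strictly before the
checkpoint, and re-executes the rest with the recorded resolved
parameters.  For deterministic scripts the final directory digest equals
an uninterrupted run's digest — asserted in the tests via a content
digest that covers relative paths and file bytes, excluding only the
snapshot store itself.

## Versioning

Publication freezes a deep snapshot — scripts included — of a tool's or
workflow's development state under a version string.  The snapshot is
hashed over a canonical serialization (keys sorted at every level,
newlines normalized, minified UTF-8 JSON, SHA-256), and that hash never
changes afterwards; development edits and reverts only ever touch the
development state.  Publishing a workflow pins every stage to a concrete
published tool version, so old workflow versions keep running old tool
versions.  Two open choices were resolved as follows:

* **Version grammar**: MAJOR.MINOR.PATCH is enforced by default (it is
  the convention the system recommends, and strictness makes round-trip
  guarantees testable); `strict_versions = FALSE` relaxes it.
  Uniqueness is always required; monotonic ordering is not.
* **Publishing a workflow whose stage references a tool's development
  version**: the stage is pinned to the tool's most recently published
  version, and publication errors if none exists.  Forcing an implicit
  tool publish would mint versions the author never named.

Archives (ZIP with a canonical `manifest.json` plus a `scripts/`
subtree, workflow archives bundling their custom tools under `tools/`)
reuse the same canonical serialization, so export → import → export is
byte-stable and content hashes survive the round trip.  Name collisions
on import are suffixed `(imported-N)`, never overwritten.

## Parameter resolution

At submission each stage's parameters resolve with the precedence
**literal binding > user input > profile value > parameter default**.
Literal bindings are the workflow author's fixed choices and are not
overridable; everything else can come from the submission (`key` or
`stage_id.key` to disambiguate), from a named input profile, or from the
tool's defaults.  Unknown keys in inputs or profiles are an error, as is
any unresolved required parameter (reported by key).  An unresolved
`${placeholder}` at command-construction time is likewise an error, not
an empty substitution — a command silently missing an argument is the
failure mode that costs cluster hours.

Batch files are UTF-8 delimited text, first row a header of parameter
keys, one job per subsequent row, submitted in row order.  The delimiter
is auto-detected between tab and comma (configurable); a row with the
wrong arity aborts with its 1-based row number.

## The backend layer

Backends implement a fixed contract (`submit`, `status`, `cancel`,
`hold`, `release`, `cluster_snapshot`, settings read/update); data comes
back in typed data objects whose metadata (label and value kind per key)
lets the core display scheduler-specific fields without knowing them.
A backend is selected by name from configuration; unknown names are
looked up as `<plugin_dir>/<name>.R` files defining `backend_<name>()`,
so adding a scheduler requires no core changes.  A deliberately
unimplemented operation raises one uniform "not supported by plugin"
condition (the UGE backend is such a stub, kept as a template).

The **local backend** runs each stage as a subprocess in the job's
working directory, capturing stdout/stderr to `stage_<id>.out|.err`
sidecars and the exit code to `stage_<id>.exit`.  The same sidecar
wrapper is emitted into generated Torque/SLURM job scripts, because
resource managers do not uniformly report per-stage exit codes and the
conditional edges need the exact code regardless of dialect.  Directive
conventions: memory is emitted as integer megabytes (`mem=...mb` /
`--mem=...`), walltime as `HH:MM:SS`; parsing a generated script
recovers the resource request exactly, which holds bit-exactly whenever
the request's memory is a whole number of megabytes — the granularity at
which users request memory in practice, and the granularity the fixture
generator draws from.

Status parsing targets the long block formats (`qstat -f`-style for
Torque, `scontrol show job`-style for SLURM) and is best-effort: state
codes map through a per-dialect table, unknown codes map to `unknown`,
and an unparseable block yields an `unknown` record with its raw text
retained rather than an exception.  Only the long forms are covered; the
brief tabular outputs are not.

## Scheduling and determinism

The engine is tick-based: each tick polls running stages (in sorted
stage order), records newly terminal ones, propagates conditions, then
launches ready stages up to a worker limit (default 2).  Independent
stages genuinely overlap — the local backend spawns real subprocesses —
but every state decision depends only on recorded exit codes, so the
terminal state of every stage and of the job is identical regardless of
completion order.  The tests perturb scheduling with random launch
jitter over repeated runs and assert identical recorded outcomes.  The
engine itself consumes no randomness.

The background updater of a deployed system is modelled by
`poll_tick()`: one explicit tick refreshes all active jobs, and a
backend outage leaves records untouched with a warning.  The production
cadence (default 5 s) is configuration; tests inject ticks manually.

## History, sharing, impersonation

Every job — including failed and cancelled ones — leaves a permanent
record: per-stage resolved parameters, both streams (capped at a
configurable size with a truncation marker), exit statuses, ISO-8601 UTC
timestamps and snapshot references.  The store is a thin persistence
boundary over one JSON document per job; any relational engine could
substitute behind the same interface.  Jobs can be shared read-only;
recipients can read records and streams but cannot cancel, delete or
resume (resume rights for shared jobs are left to the owner — the
conservative answer where the design was open).

Impersonated execution seals `user:password` with the executor's
2048-bit RSA public key at the boundary; ciphertext is all that is ever
persisted or logged.  The executor alone holds the private key,
re-authenticates against a pluggable authenticator on **every**
execution request (sessions do not bypass it), and only then spawns the
command.  A `key_id` accompanies every envelope so key rotation cleanly
invalidates old envelopes, which also covers password-change semantics
operationally: re-authentication simply fails.  The executor here runs
in-process with a documented plain-text request/response encoding; real
OS/PAM/LDAP verification and actual OS-level user switching sit behind
the authenticator port and are out of scope.

## What the fixtures emulate — and what they do not

The fixture generator produces the canonical workflow shapes (a
success/failure fork, an exit-code fork, a diamond with an exit-code
tail, a six-stage pipeline whose two preparation stages are independent,
linear chains, seeded random DAGs) with POSIX-shell stage scripts that
sleep a planned delay, touch a marker file and exit with a planned code,
plus scheduler status text with known ground truth.  Problem sizes in
the suite were chosen to exercise every semantic path while keeping runs
small: random-DAG oracle comparisons use 100 graphs of up to 10 stages,
determinism checks use 50 repeated runs, dialect round trips use 200
random requests, and stage delays are fractions of a second.

Passing these tests shows the scheduling, versioning and recording
semantics are correct; it does not show that real bioinformatics
payloads behave — the fixture scripts are inert placeholders for tools
like docking or molecular-dynamics codes, whose scientific behaviour is
explicitly not reproduced.  Nor do the tests exercise a live Torque or
SLURM installation: the dialect backends are verified against generated
script and status text, and their `submit()` correctly reports the
scheduler unavailable when `qsub`/`sbatch` are absent.

## Known limitations

* Workflow-of-workflows nesting, cross-cluster scheduling and runtime
  job-alteration requests are out of scope.
* Hold/release on the local backend uses SIGSTOP/SIGCONT; schedulers
  with richer hold semantics are reached through their own plugins.
* The history store is append-oriented and unbounded; archiving old jobs
  is the deployment's concern.
* Checkpoint eligibility being structural means some runtime-safe
  resume points (mutually exclusive conditional branches) are rejected;
  that is the intended conservative trade-off.
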