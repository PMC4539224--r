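#' Build a workflow stage
#'
#' A stage is one tool invocation within a workflow: it names the tool, the
#' tool version to use (`"dev"` until publication pins a concrete version),
#' the parameter bindings, and whether the stage is flagged as a
#' checkpoint.  Bindings map parameter keys either to literal values or to
#' the marker [user_input()], meaning the value is collected at submission
#' time.
#'
#' @param stage_id identifier, unique within the workflow.
#' @param tool tool name in the registry.
#' @param bindings named list of parameter bindings (literal or [user_input()]).
#' @param version tool version selector: `"dev"` or a published version string.
#' @param is_checkpoint flag the stage as a checkpoint; only structurally
#'   sequential stages (see [checkpoint_eligible_stages()]) may carry it.
#' @return a `stage` object.
#' @export
stage <- function(stage_id, tool, bindings = list(), version = "dev",
                  is_checkpoint = FALSE) {
  if (!nzchar(stage_id)) abort("stage_id must be non-empty")
  structure(
    list(stage_id = stage_id, tool = tool, version = version,
         bindings = bindings, is_checkpoint = isTRUE(is_checkpoint)),
    class = "stage"
  )
}

#' Marker for a parameter bound at submission time
#' @return sentinel object recognised by the parameter resolver.
#' @export
user_input <- function() structure(list(), class = "user_input")

is_user_input <- function(x) inherits(x, "user_input")

#' Conditional dependency between two stages
#'
#' An edge parent -> child that the scheduler only traverses when the
#' parent's exit status satisfies the condition: `on_success` (exit 0),
#' `on_fail` (any nonzero exit or a backend-reported abort), or
#' `on_exit_code` with a specific code.  Exit-status conditions are the
#' branching primitive: a script that exits with a chosen code steers the
#' workflow down the matching edge.
#'
#' @param parent,child stage ids; must differ.
#' @param condition `"on_success"`, `"on_fail"` or `"on_exit_code"`.
#' @param code required exit code when `condition = "on_exit_code"`.
#' @return a `stage_dependency` object.
#' @examples
#' stage_dependency("D", "E", "on_exit_code", code = 5)
#' @export
stage_dependency <- function(parent, child, condition = "on_success", code = NULL) {
  condition <- match.arg(condition, c("on_success", "on_fail", "on_exit_code"))
  if (identical(parent, child)) {
    abort(sprintf("self-dependency: stage '%s' cannot depend on itself", parent))
  }
  if (condition == "on_exit_code") {
    if (is.null(code) || is.na(suppressWarnings(as.integer(code)))) {
      abort("on_exit_code dependency requires an integer code")
    }
    code <- as.integer(code)
  } else {
    code <- NULL
  }
  structure(
    list(parent = parent, child = child, condition = condition, code = code),
    class = "stage_dependency"
  )
}

#' Assemble a workflow development state
#'
#' @param name workflow name.
#' @param stages list of [stage()] objects.
#' @param dependencies list of [stage_dependency()] edges.
#' @param description free text.
#' @return a `workflow_state` object (the mutable development version).
#' @export
workflow_state <- function(name, stages = list(), dependencies = list(),
                           description = "") {
  structure(
    list(name = name, description = description,
         stages = stages, dependencies = dependencies),
    class = "workflow_state"
  )
}

stage_ids <- function(state) vapply(state$stages, `[[`, character(1), "stage_id")

#' Validate a workflow development state
#'
#' Checks the structural well-formedness the engine relies on: dependency
#' endpoints exist, no self-dependencies or duplicate conditional edges, the
#' graph is acyclic, checkpoint flags sit only on eligible stages, and
#' bindings refer to declared parameter keys (when a registry is supplied
#' to resolve the tools).  Violations are returned, not thrown, so a
#' front-end can display all of them at once.
#'
#' @param state a [workflow_state()].
#' @param registry optional [tool_registry()] used to check that stage tools
#'   exist and bindings name real parameters.
#' @return a tibble with columns `where` (stage id or edge) and `problem`;
#'   zero rows when the workflow is valid.
#' @examples
#' w <- workflow_state("w", list(stage("A", "t"), stage("B", "t")),
#'                     list(stage_dependency("A", "B")))
#' validate_workflow(w)
#' @export
validate_workflow <- function(state, registry = NULL) {
  bad <- list()
  note <- function(where, problem) bad[[length(bad) + 1]] <<- tibble(where = where, problem = problem)

  ids <- stage_ids(state)
  if (anyDuplicated(ids)) {
    for (d in unique(ids[duplicated(ids)])) note(d, "duplicate stage id")
  }
  seen_edges <- character()
  for (dep in state$dependencies) {
    lab <- sprintf("%s->%s", dep$parent, dep$child)
    if (identical(dep$parent, dep$child)) note(lab, "self-dependency")
    if (!dep$parent %in% ids) note(lab, sprintf("unknown parent stage '%s'", dep$parent))
    if (!dep$child %in% ids) note(lab, sprintf("unknown child stage '%s'", dep$child))
    key <- paste(dep$parent, dep$child, dep$condition, dep$code %||% "", sep = "\r")
    if (key %in% seen_edges) note(lab, "duplicate dependency")
    seen_edges <- c(seen_edges, key)
  }
  if (length(ids) && !any(vapply(bad, function(b) grepl("unknown|self", b$problem), logical(1)))) {
    g <- dependency_graph(state)
    if (!igraph::is_dag(g)) {
      cyc <- tryCatch(
        paste(names(igraph::feedback_arc_set(g)), collapse = ","),
        error = function(e) "")
      note(if (nzchar(cyc)) cyc else "graph", "cycle in dependency graph")
    } else {
      eligible <- checkpoint_eligible_stages(state)
      for (s in state$stages) {
        if (s$is_checkpoint && !s$stage_id %in% eligible) {
          note(s$stage_id, "checkpoint flag on a stage that runs in parallel with others")
        }
      }
    }
  }
  if (!is.null(registry)) {
    for (s in state$stages) {
      def <- tryCatch(registry$tool_dev(s$tool), error = function(e) NULL)
      if (is.null(def)) {
        note(s$stage_id, sprintf("unknown tool '%s'", s$tool))
        next
      }
      keys <- vapply(def$parameters, `[[`, character(1), "key")
      for (k in names(s$bindings)) {
        if (!k %in% keys) {
          note(s$stage_id, sprintf("binding references unknown parameter '%s'", k))
        }
      }
    }
  }
  if (length(bad)) dplyr::bind_rows(bad) else tibble(where = character(), problem = character())
}

# igraph view of the dependency structure (conditions ignored)
dependency_graph <- function(state) {
  ids <- stage_ids(state)
  edges <- unlist(lapply(state$dependencies, function(d) c(d$parent, d$child)))
  igraph::graph_from_data_frame(
    if (length(edges)) {
      data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)])
    } else {
      data.frame(from = character(), to = character())
    },
    directed = TRUE,
    vertices = data.frame(name = ids)
  )
}

#' Which stages may serve as checkpoints?
#'
#' A job can only be resumed from a point where all forks of the workflow
#' have converged: a snapshot taken at the start of a stage that runs in
#' parallel with another stage would capture the working directory
#' mid-flight for its sibling.  Structurally, a stage is
#' checkpoint-eligible iff it is comparable to every other stage in the
#' reachability order of the dependency graph — for every other stage t,
#' either the stage reaches t or t reaches it.  Edge conditions are
#' deliberately ignored: two conditional branches that can never co-run at
#' runtime still disqualify each other, a conservative reading that keeps
#' eligibility a property of the graph alone.
#'
#' @param state a valid (acyclic) [workflow_state()].
#' @return character vector of eligible stage ids, sorted.
#' @examples
#' # diamond A -> {B, C} -> D -> E: B and C are incomparable, so only
#' # A, D and E are eligible
#' w <- workflow_state("w",
#'   lapply(c("A", "B", "C", "D", "E"), stage, tool = "t"),
#'   list(stage_dependency("A", "B"), stage_dependency("A", "C"),
#'        stage_dependency("B", "D"), stage_dependency("C", "D"),
#'        stage_dependency("D", "E", "on_exit_code", code = 5)))
#' checkpoint_eligible_stages(w)
#' @export
checkpoint_eligible_stages <- function(state) {
  g <- dependency_graph(state)
  if (!igraph::is_dag(g)) abort("dependency graph is cyclic")
  ids <- stage_ids(state)
  n <- length(ids)
  if (n == 0) return(character())
  # reach[i, j] == TRUE iff i reaches j (including i == j)
  reach <- igraph::distances(g, mode = "out") < Inf
  comparable <- reach | t(reach)
  sort(ids[rowSums(comparable) == n])
}

# canonical (hash-ready) representation of a workflow's content;
# pins must be a named map stage_id -> tool version string for published
# versions, or NULL for the dev state
workflow_canonical <- function(state, pins = NULL) {
  ord <- order(stage_ids(state), method = "radix")
  list(
    name = state$name,
    description = state$description,
    stages = lapply(state$stages[ord], function(s) {
      list(stage_id = s$stage_id, tool = s$tool,
           version = pins[[s$stage_id]] %||% s$version,
           is_checkpoint = s$is_checkpoint,
           bindings = lapply(s$bindings, function(b) {
             if (is_user_input(b)) "__user_input__" else b
           }))
    }),
    dependencies = lapply(
      state$dependencies[order(vapply(state$dependencies, function(d) {
        paste(d$parent, d$child, d$condition, d$code %||% "")
      }, character(1)), method = "radix")],
      function(d) list(parent = d$parent, child = d$child,
                       condition = d$condition, code = d$code)
    )
  )
}

#' @export
print.workflow_state <- function(x, ...) {
  cat(sprintf("<workflow_state> %s: %d stage(s), %d dependenc%s\n",
              x$name, length(x$stages), length(x$dependencies),
              if (length(x$dependencies) == 1) "y" else "ies"))
  for (d in x$dependencies) {
    cat(sprintf("  %s -> %s [%s%s]\n", d$parent, d$child, d$condition,
                if (is.null(d$code)) "" else paste0(" ", d$code)))
  }
  invisible(x)
}
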