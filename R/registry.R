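#' Tool and workflow registry with immutable versioning
#'
#' The registry is the stateful store behind the library: it holds the
#' mutable development state of every tool and workflow, the frozen
#' published versions, per-object access control, and named input
#' profiles.  Publishing takes a deep snapshot of the development state
#' (scripts included; workflow tool references pinned to concrete
#' published tool versions) and freezes it under a version string; the
#' snapshot's content hash never changes afterwards, however the
#' development state is edited or reverted.
#'
#' Version strings follow MAJOR.MINOR.PATCH.  Strict grammar checking is
#' on by default (`strict_versions = TRUE`); uniqueness is always
#' required, monotonic ordering is not.
#'
#' @param strict_versions enforce the MAJOR.MINOR.PATCH grammar on publish.
#' @return `tool_registry()` returns a `ToolRegistry` R6 object.
#' @examples
#' reg <- tool_registry()
#' reg$create_tool(tool_definition("echo", "echo hi"), user = "ann")
#' v <- reg$publish_tool("echo", "1.0.0", user = "ann")
#' v$content_hash
#' @export
tool_registry <- function(strict_versions = TRUE) {
  ToolRegistry$new(strict_versions = strict_versions)
}

RIGHTS <- c("RUN", "EXPORT", "EDIT_DEV", "PUBLISH", "ADMIN")

acl_new <- function(creator) {
  list(creator = creator, public_run = FALSE, grants = list())
}

is_semver <- function(v) grepl("^(0|[1-9][0-9]*)\\.(0|[1-9][0-9]*)\\.(0|[1-9][0-9]*)$", v)

#' @rdname tool_registry
#' @export
ToolRegistry <- R6::R6Class("ToolRegistry",
  public = list(
    #' @field strict_versions enforce MAJOR.MINOR.PATCH on publish.
    strict_versions = TRUE,

    #' @description Create a registry.
    #' @param strict_versions enforce the version grammar on publish.
    initialize = function(strict_versions = TRUE) {
      self$strict_versions <- isTRUE(strict_versions)
      private$tools <- list()
      private$workflows <- list()
      private$profiles <- list()
    },

    ## ---- tools -------------------------------------------------------

    #' @description Register a new tool; the definition becomes its
    #'   development state and `user` its creator.
    #' @param definition a [tool_definition()].
    #' @param user creator.
    create_tool = function(definition, user = "local") {
      stopifnot(inherits(definition, "tool_definition"))
      if (definition$name %in% names(private$tools)) {
        abort(sprintf("tool '%s' already exists", definition$name))
      }
      private$tools[[definition$name]] <-
        list(dev = definition, published = list(), acl = acl_new(user))
      invisible(definition$name)
    },

    #' @description Replace a tool's development state (EDIT_DEV right).
    #' @param name tool name.
    #' @param definition new [tool_definition()] (same name).
    #' @param user acting user.
    update_tool_dev = function(name, definition, user = "local") {
      rec <- private$get_tool(name)
      private$require_right(rec$acl, user, "EDIT_DEV", name)
      stopifnot(inherits(definition, "tool_definition"))
      if (!identical(definition$name, name)) abort("renaming a tool is not supported")
      private$tools[[name]]$dev <- definition
      invisible(name)
    },

    #' @description Development state of a tool.
    #' @param name tool name.
    tool_dev = function(name) private$get_tool(name)$dev,

    #' @description List tool names.
    tool_names = function() names(private$tools),

    #' @description Published versions of a tool, newest last.
    #' @param name tool name.
    tool_versions = function(name) private$get_tool(name)$published,

    #' @description A specific published tool version.
    #' @param name tool name.
    #' @param version version string.
    tool_version = function(name, version) {
      pub <- private$get_tool(name)$published
      if (!version %in% names(pub)) {
        abort(sprintf("tool '%s' has no published version '%s'", name, version))
      }
      pub[[version]]
    },

    #' @description Freeze the development state of a tool as an immutable
    #'   published version (PUBLISH right).
    #' @param name tool name.
    #' @param version version string, unused so far for this tool.
    #' @param user acting user.
    publish_tool = function(name, version, user = "local") {
      rec <- private$get_tool(name)
      private$require_right(rec$acl, user, "PUBLISH", name)
      private$check_version_string(version, names(rec$published))
      content <- tool_canonical(rec$dev)
      ver <- list(version_string = version, content = content,
                  content_hash = content_hash(content),
                  created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
      private$tools[[name]]$published[[version]] <- ver
      ver
    },

    #' @description Revert a tool's development state to a published
    #'   version's content; the published list is untouched.
    #' @param name tool name.
    #' @param version version string to revert to.
    #' @param user acting user (EDIT_DEV right).
    revert_tool = function(name, version, user = "local") {
      rec <- private$get_tool(name)
      private$require_right(rec$acl, user, "EDIT_DEV", name)
      ver <- self$tool_version(name, version)
      private$tools[[name]]$dev <- tool_from_canonical(ver$content)
      invisible(private$tools[[name]]$dev)
    },

    ## ---- workflows ---------------------------------------------------

    #' @description Register a new workflow from a development state.
    #' @param state a [workflow_state()].
    #' @param user creator.
    create_workflow = function(state, user = "local") {
      stopifnot(inherits(state, "workflow_state"))
      if (state$name %in% names(private$workflows)) {
        abort(sprintf("workflow '%s' already exists", state$name))
      }
      private$workflows[[state$name]] <-
        list(dev = state, published = list(), acl = acl_new(user))
      invisible(state$name)
    },

    #' @description Replace a workflow's development state (EDIT_DEV).
    #' @param name workflow name.
    #' @param state new [workflow_state()] (same name).
    #' @param user acting user.
    update_workflow_dev = function(name, state, user = "local") {
      rec <- private$get_workflow(name)
      private$require_right(rec$acl, user, "EDIT_DEV", name)
      if (!identical(state$name, name)) abort("renaming a workflow is not supported")
      private$workflows[[name]]$dev <- state
      invisible(name)
    },

    #' @description Development state of a workflow.
    #' @param name workflow name.
    workflow_dev = function(name) private$get_workflow(name)$dev,

    #' @description List workflow names.
    workflow_names = function() names(private$workflows),

    #' @description Published versions of a workflow.
    #' @param name workflow name.
    workflow_versions = function(name) private$get_workflow(name)$published,

    #' @description A specific published workflow version.
    #' @param name workflow name.
    #' @param version version string.
    workflow_version = function(name, version) {
      pub <- private$get_workflow(name)$published
      if (!version %in% names(pub)) {
        abort(sprintf("workflow '%s' has no published version '%s'", name, version))
      }
      pub[[version]]
    },

    #' @description Publish a workflow version.  The development state must
    #'   validate; every stage referencing a tool's development version is
    #'   pinned to that tool's most recently published version (an error if
    #'   the tool has none), so a published workflow never depends on
    #'   mutable state.
    #' @param name workflow name.
    #' @param version version string.
    #' @param user acting user (PUBLISH right).
    publish_workflow = function(name, version, user = "local") {
      rec <- private$get_workflow(name)
      private$require_right(rec$acl, user, "PUBLISH", name)
      private$check_version_string(version, names(rec$published))
      violations <- validate_workflow(rec$dev, self)
      if (nrow(violations)) {
        abort(sprintf("workflow '%s' does not validate: %s", name,
                      paste(violations$where, violations$problem,
                            sep = ": ", collapse = "; ")))
      }
      pins <- list()
      tool_snapshots <- list()
      for (s in rec$dev$stages) {
        trec <- private$get_tool(s$tool)
        pin <- s$version
        if (identical(pin, "dev")) {
          if (length(trec$published) == 0) {
            abort(sprintf(
              "stage '%s' references the development version of tool '%s', which has no published version to pin",
              s$stage_id, s$tool))
          }
          pin <- names(trec$published)[[length(trec$published)]]
        } else if (!pin %in% names(trec$published)) {
          abort(sprintf("stage '%s' pins unknown version '%s' of tool '%s'",
                        s$stage_id, pin, s$tool))
        }
        pins[[s$stage_id]] <- pin
        tool_snapshots[[paste(s$tool, pin, sep = "@")]] <- trec$published[[pin]]
      }
      content <- workflow_canonical(rec$dev, pins)
      ver <- list(version_string = version, content = content, pins = pins,
                  tools = tool_snapshots,
                  content_hash = content_hash(content),
                  created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
      private$workflows[[name]]$published[[version]] <- ver
      ver
    },

    #' @description Revert a workflow's development state to a published
    #'   version's content.
    #' @param name workflow name.
    #' @param version version string.
    #' @param user acting user (EDIT_DEV right).
    revert_workflow = function(name, version, user = "local") {
      rec <- private$get_workflow(name)
      private$require_right(rec$acl, user, "EDIT_DEV", name)
      ver <- self$workflow_version(name, version)
      private$workflows[[name]]$dev <- workflow_from_canonical(ver$content)
      invisible(private$workflows[[name]]$dev)
    },

    ## ---- permissions -------------------------------------------------

    #' @description Grant rights on a tool or workflow (caller needs ADMIN).
    #' @param kind `"tool"` or `"workflow"`.
    #' @param name object name.
    #' @param subject user receiving the rights.
    #' @param rights character vector, subset of
    #'   RUN, EXPORT, EDIT_DEV, PUBLISH, ADMIN.
    #' @param user acting user.
    grant = function(kind, name, subject, rights, user = "local") {
      rec <- private$get_any(kind, name)
      private$require_right(rec$acl, user, "ADMIN", name)
      rights <- match.arg(rights, RIGHTS, several.ok = TRUE)
      cur <- rec$acl$grants[[subject]] %||% character()
      private$set_acl(kind, name, grants = modifyList(
        rec$acl$grants, setNames(list(union(cur, rights)), subject)))
      invisible(TRUE)
    },

    #' @description Revoke rights.  The creator's ADMIN right can never be
    #'   revoked, by anyone.
    #' @param kind,name object.
    #' @param subject user losing the rights.
    #' @param rights rights to remove.
    #' @param user acting user (ADMIN).
    revoke = function(kind, name, subject, rights, user = "local") {
      rec <- private$get_any(kind, name)
      private$require_right(rec$acl, user, "ADMIN", name)
      if (identical(subject, rec$acl$creator) && "ADMIN" %in% rights) {
        abort("the creator's ADMIN right cannot be revoked")
      }
      cur <- rec$acl$grants[[subject]] %||% character()
      private$set_acl(kind, name, grants = modifyList(
        rec$acl$grants, setNames(list(setdiff(cur, rights)), subject)))
      invisible(TRUE)
    },

    #' @description Mark a tool or workflow public: every user on the
    #'   system may run it (and only run it).
    #' @param kind,name object.
    #' @param public logical.
    #' @param user acting user (ADMIN).
    set_public = function(kind, name, public = TRUE, user = "local") {
      rec <- private$get_any(kind, name)
      private$require_right(rec$acl, user, "ADMIN", name)
      private$set_acl(kind, name, public_run = isTRUE(public))
      invisible(TRUE)
    },

    #' @description Does `user` hold `right` on the object?  True for the
    #'   creator (always), for an explicit grant, via ADMIN (which implies
    #'   every other right), or — for RUN only — via the public flag.
    #' @param user user name.
    #' @param kind,name object.
    #' @param right one of RUN, EXPORT, EDIT_DEV, PUBLISH, ADMIN.
    check_permission = function(user, kind, name, right) {
      rec <- private$get_any(kind, name)
      acl_allows(rec$acl, user, match.arg(right, RIGHTS))
    },

    #' @description Access-control record of an object (creator, public
    #'   flag, grants).
    #' @param kind,name object.
    acl = function(kind, name) private$get_any(kind, name)$acl,

    ## ---- input profiles ---------------------------------------------

    #' @description Save a named input profile: a reusable set of default
    #'   parameter values for a tool or workflow, overridable per
    #'   submission.
    #' @param profile an [input_profile()].
    save_profile = function(profile) {
      stopifnot(inherits(profile, "input_profile"))
      private$profiles[[profile$name]] <- profile
      invisible(profile$name)
    },

    #' @description Fetch a saved profile by name.
    #' @param name profile name.
    profile = function(name) {
      if (!name %in% names(private$profiles)) abort(sprintf("no profile '%s'", name))
      private$profiles[[name]]
    },

    #' @description Import support: register a tool directly from frozen
    #'   version content (used by [import_archive()]).
    #' @param content canonical tool content.
    #' @param version version string.
    #' @param user importing user (becomes creator).
    #' @param name optional name override (collision suffixing).
    adopt_tool_version = function(content, version, user = "local", name = NULL) {
      name <- name %||% content$name
      def <- tool_from_canonical(content, name = name)
      self$create_tool(def, user = user)
      rec <- private$get_tool(name)
      private$check_version_string(version, character())
      private$tools[[name]]$published[[version]] <-
        list(version_string = version, content = tool_canonical(def),
             content_hash = content_hash(tool_canonical(def)),
             created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
      invisible(name)
    }
  ),

  private = list(
    tools = NULL, workflows = NULL, profiles = NULL,

    get_tool = function(name) {
      if (!name %in% names(private$tools)) abort(sprintf("unknown tool '%s'", name))
      private$tools[[name]]
    },
    get_workflow = function(name) {
      if (!name %in% names(private$workflows)) abort(sprintf("unknown workflow '%s'", name))
      private$workflows[[name]]
    },
    get_any = function(kind, name) {
      switch(match.arg(kind, c("tool", "workflow")),
             tool = private$get_tool(name),
             workflow = private$get_workflow(name))
    },
    set_acl = function(kind, name, public_run = NULL, grants = NULL) {
      slot <- if (kind == "tool") "tools" else "workflows"
      if (!is.null(public_run)) private[[slot]][[name]]$acl$public_run <- public_run
      if (!is.null(grants)) private[[slot]][[name]]$acl$grants <- grants
    },
    require_right = function(acl, user, right, name) {
      if (!acl_allows(acl, user, right)) {
        abort(sprintf("user '%s' lacks %s permission on '%s'", user, right, name))
      }
    },
    check_version_string = function(version, existing) {
      if (version %in% existing) {
        abort(sprintf("version '%s' already published", version))
      }
      if (self$strict_versions && !is_semver(version)) {
        abort(sprintf("version '%s' does not match MAJOR.MINOR.PATCH", version))
      }
    }
  )
)

acl_allows <- function(acl, user, right) {
  if (identical(user, acl$creator)) return(TRUE)
  granted <- acl$grants[[user]] %||% character()
  if ("ADMIN" %in% granted) return(TRUE)
  if (right %in% granted) return(TRUE)
  right == "RUN" && isTRUE(acl$public_run)
}

# rebuild value objects from canonical (frozen) content
tool_from_canonical <- function(content, name = NULL) {
  tool_definition(
    name = name %||% content$name,
    description = content$description,
    command_template = content$command_template,
    parameters = lapply(content$parameters, function(p) {
      parameter_spec(p$key, p$label, p$kind, p$required, p$default,
                     if (length(p$choices)) unlist(p$choices))
    }),
    expected_outputs = unlist(content$expected_outputs) %||% character(),
    resources = resource_request(content$resources$nodes,
                                 content$resources$cores_per_node,
                                 content$resources$memory,
                                 content$resources$walltime,
                                 content$resources$queue),
    scripts = if (length(content$scripts)) {
      setNames(vapply(content$scripts, identity, character(1)), names(content$scripts))
    } else {
      character()
    }
  )
}

workflow_from_canonical <- function(content, name = NULL) {
  workflow_state(
    name = name %||% content$name,
    description = content$description,
    stages = lapply(content$stages, function(s) {
      stage(s$stage_id, s$tool, version = s$version,
            is_checkpoint = isTRUE(s$is_checkpoint),
            bindings = lapply(s$bindings, function(b) {
              if (identical(b, "__user_input__")) user_input() else b
            }))
    }),
    dependencies = lapply(content$dependencies, function(d) {
      stage_dependency(d$parent, d$child, d$condition, d$code)
    })
  )
}
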