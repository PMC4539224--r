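#' Define a command-line tool
#'
#' A tool is anything runnable from a terminal: an installed program or a
#' custom script.  Its definition records the command template (with
#' `${key}` placeholders for parameters), the parameter specifications, the
#' resources the scheduler should allocate, the filename patterns of
#' expected outputs, and any script files that travel with the tool.  The
#' definition returned here is the mutable development state; publishing it
#' through a registry freezes an immutable version.
#'
#' @param name tool name, unique within a registry.
#' @param command_template command line with `${key}` placeholders, each of
#'   which must match exactly one parameter key.
#' @param parameters list of [parameter_spec()] objects.
#' @param resources a [resource_request()].
#' @param description free text.
#' @param expected_outputs character vector of output filename patterns.
#' @param scripts named character vector: relative path -> file content.
#'   Paths must stay inside the tool's own directory subtree (no absolute
#'   paths, no `..` escapes).
#' @return a `tool_definition` object.
#' @examples
#' tool_definition(
#'   "align", "sh align.sh ${reads} ${ref}",
#'   parameters = list(parameter_spec("reads", kind = "file", required = TRUE),
#'                     parameter_spec("ref", kind = "file", required = TRUE)),
#'   scripts = c("align.sh" = "#!/bin/sh\nexit 0\n"))
#' @export
tool_definition <- function(name, command_template, parameters = list(),
                            resources = resource_request(),
                            description = "", expected_outputs = character(),
                            scripts = character()) {
  if (!nzchar(name)) abort("tool name must be non-empty")
  keys <- vapply(parameters, function(p) p$key, character(1))
  if (anyDuplicated(keys)) {
    abort(sprintf("duplicate parameter key(s): %s",
                  paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  # ${SCRIPTS} is reserved: the engine substitutes the stage's script
  # directory there at launch time
  for (ph in setdiff(template_placeholders(command_template), "SCRIPTS")) {
    if (!ph %in% keys) {
      abort(sprintf("placeholder '${%s}' in command template matches no parameter", ph))
    }
  }
  stopifnot(inherits(resources, "resource_request"))
  scripts <- validate_scripts(scripts)
  structure(
    list(name = name, description = description,
         command_template = command_template,
         parameters = parameters, expected_outputs = as.character(expected_outputs),
         resources = resources, scripts = scripts),
    class = "tool_definition"
  )
}

#' Extract `${key}` placeholders from a command template
#'
#' @param template a command template string.
#' @return character vector of unique placeholder keys, in order of first use.
#' @examples
#' template_placeholders("prog ${a} -o ${b} ${a}")
#' @export
template_placeholders <- function(template) {
  m <- gregexpr("\\$\\{([A-Za-z_][A-Za-z0-9_]*)\\}", template)
  hits <- regmatches(template, m)[[1]]
  unique(sub("^\\$\\{(.*)\\}$", "\\1", hits))
}

#' Substitute resolved parameter values into a command template
#'
#' Unresolved placeholders are an error, never an empty substitution: a
#' command silently missing an argument is the kind of failure that only
#' surfaces hours into a run.
#'
#' @param template command template with `${key}` placeholders.
#' @param values named list of resolved parameter values.
#' @return the resolved command string.
#' @examples
#' resolve_command("prog ${a}", list(a = "x"))
#' @export
resolve_command <- function(template, values) {
  needed <- template_placeholders(template)
  missing <- setdiff(needed, names(values))
  if (length(missing)) {
    abort(sprintf("unresolved placeholder(s) in command template: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- template
  for (key in needed) {
    v <- values[[key]]
    if (is.logical(v)) v <- if (isTRUE(v)) "1" else "0"
    out <- gsub(sprintf("${%s}", key), as.character(v), out, fixed = TRUE)
  }
  out
}

# script paths must be relative, normalized and confined to the tool subtree
validate_scripts <- function(scripts) {
  if (length(scripts) == 0) return(setNames(character(), character()))
  paths <- names(scripts)
  if (is.null(paths) || any(!nzchar(paths))) abort("scripts must be a named character vector")
  for (p in paths) {
    parts <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (startsWith(p, "/") || grepl("^[A-Za-z]:", p) ||
        any(parts %in% c("..", "")) || p != paste(parts, collapse = "/")) {
      abort(sprintf("script path '%s' is not a normalized relative path inside the tool directory", p))
    }
  }
  storage.mode(scripts) <- "character"
  scripts[order(paths, method = "radix")]
}

# canonical (hash-ready) representation of a tool's content
tool_canonical <- function(def) {
  list(
    name = def$name,
    description = def$description,
    command_template = def$command_template,
    parameters = lapply(def$parameters, function(p) {
      list(key = p$key, label = p$label, kind = p$kind,
           required = p$required, default = p$default, choices = as.list(p$choices))
    }),
    expected_outputs = as.list(def$expected_outputs),
    resources = list(nodes = def$resources$nodes,
                     cores_per_node = def$resources$cores_per_node,
                     memory = def$resources$memory,
                     walltime = def$resources$walltime,
                     queue = def$resources$queue),
    scripts = as.list(def$scripts)
  )
}

#' @export
print.tool_definition <- function(x, ...) {
  cat(sprintf("<tool_definition> %s\n  command: %s\n  parameters: %s\n",
              x$name, x$command_template,
              paste(vapply(x$parameters, `[[`, character(1), "key"), collapse = ", ")))
  invisible(x)
}
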