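#' Declare a tool parameter
#'
#' Each tool carries an ordered list of parameter specifications that drive
#' both command-line substitution and the automatically generated input
#' forms of a front-end.  A parameter has a machine key (used as the
#' `${key}` placeholder in the command template), a human label, a kind,
#' and optionally a default and — for choice parameters — the permitted
#' values.
#'
#' @param key identifier; must match `[A-Za-z_][A-Za-z0-9_]*`.
#' @param label human-readable label; defaults to the key.
#' @param kind one of `"text"`, `"number"`, `"file"`, `"choice"`, `"flag"`.
#' @param required logical; must a value be resolvable at submission?
#' @param default optional default value; must satisfy `kind`.
#' @param choices character vector of permitted values (`kind = "choice"` only).
#' @return a `parameter_spec` object (a validated list).
#' @examples
#' parameter_spec("emtol", "Energy tolerance", kind = "number", default = 10)
#' @export
parameter_spec <- function(key, label = key, kind = "text", required = FALSE,
                           default = NULL, choices = NULL) {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", key)) {
    abort(sprintf("invalid parameter key '%s'", key))
  }
  kind <- match.arg(kind, c("text", "number", "file", "choice", "flag"))
  if (kind == "choice") {
    if (is.null(choices) || length(choices) < 1) {
      abort(sprintf("choice parameter '%s' needs at least one choice", key))
    }
    choices <- as.character(choices)
  } else if (!is.null(choices)) {
    abort(sprintf("parameter '%s': choices are only valid for kind = 'choice'", key))
  }
  if (!is.null(default)) check_param_value(key, kind, choices, default)
  structure(
    list(key = key, label = label, kind = kind, required = isTRUE(required),
         default = default, choices = choices),
    class = "parameter_spec"
  )
}

# value conformance for one parameter kind; used for defaults, profiles and
# user inputs alike
check_param_value <- function(key, kind, choices, value) {
  ok <- switch(kind,
    text   = is.character(value) || is.numeric(value),
    file   = is.character(value) && length(value) == 1,
    number = (is.numeric(value) ||
                (is.character(value) && !is.na(suppressWarnings(as.numeric(value))))),
    choice = as.character(value) %in% choices,
    flag   = is.logical(value) || value %in% c(0, 1, "0", "1", "true", "false")
  )
  if (!isTRUE(ok)) {
    abort(sprintf("value '%s' does not satisfy kind '%s' of parameter '%s'",
                  paste(format(value), collapse = ","), kind, key))
  }
  invisible(TRUE)
}

#' Specify the cluster resources a tool requests
#'
#' Resource requests are what the job-script generator translates into
#' scheduler directives: node and per-node core counts, memory and a
#' wall-clock limit, plus an optional queue/partition.  Memory is stored in
#' bytes and walltime in seconds, whatever the scheduler dialect later
#' prints.
#'
#' @param nodes,cores_per_node positive integer counts.
#' @param memory requested memory in bytes (> 0).
#' @param walltime wall-clock limit in seconds (> 0).
#' @param queue optional queue (Torque) / partition (SLURM) name.
#' @return a `resource_request` object.
#' @examples
#' resource_request(nodes = 1, cores_per_node = 4,
#'                  memory = 4 * 1024^3, walltime = 3600)
#' @export
resource_request <- function(nodes = 1, cores_per_node = 1,
                             memory = 1024^3, walltime = 3600, queue = NULL) {
  nodes <- as.integer(nodes); cores_per_node <- as.integer(cores_per_node)
  if (is.na(nodes) || nodes < 1) abort("nodes must be a positive integer")
  if (is.na(cores_per_node) || cores_per_node < 1) {
    abort("cores_per_node must be a positive integer")
  }
  memory <- as.numeric(memory); walltime <- as.numeric(walltime)
  if (is.na(memory) || memory <= 0) abort("memory must be > 0 bytes")
  if (is.na(walltime) || walltime <= 0) abort("walltime must be > 0 seconds")
  structure(
    list(nodes = nodes, cores_per_node = cores_per_node,
         memory = memory, walltime = walltime, queue = queue),
    class = "resource_request"
  )
}

#' @export
print.resource_request <- function(x, ...) {
  cat(sprintf("<resource_request> %d node(s) x %d core(s), %.0f MB, %ds%s\n",
              x$nodes, x$cores_per_node, x$memory / 1024^2, as.integer(x$walltime),
              if (is.null(x$queue)) "" else paste0(", queue ", x$queue)))
  invisible(x)
}
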