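#' Named sets of default parameter values
#'
#' An input profile pre-fills parameter values for a tool or workflow so a
#' user submitting the same pipeline many times only supplies the values
#' that change.  At submission, explicit user inputs override profile
#' values, which in turn override the parameters' own defaults.
#'
#' @param name profile name.
#' @param target `"tool:NAME"` or `"workflow:NAME"` the profile applies to.
#' @param values named list: parameter key (for workflows,
#'   `"stage_id.key"`) -> value.
#' @param owner user who owns the profile.
#' @return an `input_profile` object.
#' @export
input_profile <- function(name, target, values = list(), owner = "local") {
  if (!nzchar(name)) abort("profile name must be non-empty")
  if (length(values) && (is.null(names(values)) || any(!nzchar(names(values))))) {
    abort("profile values must be a named list")
  }
  structure(list(name = name, target = target, values = values, owner = owner),
            class = "input_profile")
}

#' Resolve parameter values from inputs, profile and defaults
#'
#' Builds the final parameter map for one tool invocation with the
#' precedence user inputs > profile > parameter default, then verifies
#' that every required parameter is resolved and every value satisfies its
#' parameter's kind.
#'
#' @param parameters list of [parameter_spec()] objects.
#' @param user_inputs named list of values supplied at submission.
#' @param profile optional [input_profile()] (or a plain named list of
#'   profile values).
#' @return named list of resolved values, one entry per resolvable key.
#' @examples
#' ps <- list(parameter_spec("p1", required = TRUE), parameter_spec("p2"))
#' apply_input_profile(ps, user_inputs = list(p2 = "b"),
#'                     profile = input_profile("x", "tool:t", list(p1 = "a")))
#' @export
apply_input_profile <- function(parameters, user_inputs = list(), profile = NULL) {
  pvals <- if (inherits(profile, "input_profile")) profile$values else profile %||% list()
  keys <- vapply(parameters, `[[`, character(1), "key")
  for (nm in names(user_inputs)) {
    if (!nm %in% keys) abort(sprintf("unknown parameter '%s' in inputs", nm))
  }
  for (nm in names(pvals)) {
    if (!nm %in% keys) abort(sprintf("unknown parameter '%s' in profile", nm))
  }
  resolved <- list()
  missing <- character()
  for (p in parameters) {
    v <- user_inputs[[p$key]] %||% pvals[[p$key]] %||% p$default
    if (is.null(v)) {
      if (p$required) missing <- c(missing, p$key)
      next
    }
    check_param_value(p$key, p$kind, p$choices, v)
    resolved[[p$key]] <- v
  }
  if (length(missing)) {
    abort(sprintf("missing required parameter(s): %s", paste(missing, collapse = ", ")))
  }
  resolved
}
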