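#' Export a published version to a portable archive
#'
#' A published tool or workflow version can be exported to a ZIP archive
#' and imported into another registry instance — the mechanism by which
#' collaborating groups exchange pipelines.  The archive holds
#' `manifest.json` (the canonical serialization of the frozen version,
#' byte-stable across export/import/export cycles) and a `scripts/`
#' subtree with the bundled script files.  Workflow archives additionally
#' bundle the pinned custom-tool versions under `tools/`; programs
#' installed system-wide are referenced by name only, not bundled.
#'
#' @param registry a [tool_registry()].
#' @param kind `"tool"` or `"workflow"`.
#' @param name object name.
#' @param version published version string to export.
#' @param path output file path (`.zip`).
#' @param user acting user; needs the EXPORT right.
#' @return `path`, invisibly.
#' @seealso [import_archive()]
#' @export
export_archive <- function(registry, kind, name, version, path, user = "local") {
  kind <- match.arg(kind, c("tool", "workflow"))
  if (!registry$check_permission(user, kind, name, "EXPORT")) {
    abort(sprintf("user '%s' lacks EXPORT permission on '%s'", user, name))
  }
  stage_dir <- tempfile("sfexport")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)

  if (kind == "tool") {
    ver <- registry$tool_version(name, version)
    write_manifest(stage_dir, kind, ver)
    write_script_tree(file.path(stage_dir, "scripts"), ver$content$scripts)
  } else {
    ver <- registry$workflow_version(name, version)
    write_manifest(stage_dir, kind, ver)
    for (tag in names(ver$tools)) {
      tdir <- file.path(stage_dir, "tools", gsub("[^A-Za-z0-9._@-]", "_", tag))
      dir.create(tdir, recursive = TRUE)
      tv <- ver$tools[[tag]]
      writeLines(canonical_json(list(kind = "tool",
                                     version_string = tv$version_string,
                                     content = tv$content)),
                 file.path(tdir, "manifest.json"), useBytes = TRUE)
      write_script_tree(file.path(tdir, "scripts"), tv$content$scripts)
    }
  }
  outpath <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(getwd(), path)
  zip::zip(zipfile = outpath, root = stage_dir,
           files = list.files(stage_dir), mode = "cherry-pick")
  invisible(outpath)
}

write_manifest <- function(dir, kind, ver) {
  writeLines(canonical_json(list(kind = kind, version_string = ver$version_string,
                                 content = ver$content)),
             file.path(dir, "manifest.json"), useBytes = TRUE)
}

write_script_tree <- function(dir, scripts) {
  for (rel in names(scripts)) {
    target <- file.path(dir, rel)
    dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
    # write bytes exactly; scripts are newline-normalized text
    con <- file(target, "wb")
    writeBin(charToRaw(scripts[[rel]]), con)
    close(con)
  }
}

#' Import an archive into a registry
#'
#' Recreates the archived version in `registry` with `user` as creator.
#' The manifest is the authoritative content: the canonical content hash
#' of the imported version equals the exported one.  If the name is
#' already taken, the import is renamed with an `(imported-N)` suffix
#' rather than overwriting.
#'
#' @param registry a [tool_registry()].
#' @param path archive file.
#' @param user importing user (becomes creator of the imported objects).
#' @return list with `kind`, `name` (possibly suffixed) and `version`.
#' @export
import_archive <- function(registry, path, user = "local") {
  if (!file.exists(path)) abort(sprintf("archive '%s' does not exist", path))
  exdir <- tempfile("sfimport")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  ok <- tryCatch({ zip::unzip(path, exdir = exdir); TRUE },
                 error = function(e) FALSE)
  manifest_path <- file.path(exdir, "manifest.json")
  if (!ok || !file.exists(manifest_path)) abort("malformed archive: no readable manifest")
  manifest <- tryCatch(
    jsonlite::fromJSON(read_text(manifest_path), simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(manifest) || is.null(manifest$kind) || is.null(manifest$content)) {
    abort("malformed archive: invalid manifest")
  }

  if (manifest$kind == "tool") {
    nm <- free_name(manifest$content$name, registry$tool_names())
    registry$adopt_tool_version(normalize_tool_content(manifest$content),
                                manifest$version_string, user = user, name = nm)
    list(kind = "tool", name = nm, version = manifest$version_string)
  } else if (manifest$kind == "workflow") {
    # bundled tools first; remap names on collision
    remap <- c()
    tool_dirs <- list.dirs(file.path(exdir, "tools"), recursive = FALSE)
    for (tdir in tool_dirs) {
      tman <- jsonlite::fromJSON(read_text(file.path(tdir, "manifest.json")),
                                 simplifyVector = FALSE)
      tnm <- free_name(tman$content$name, registry$tool_names())
      remap[tman$content$name] <- tnm
      registry$adopt_tool_version(normalize_tool_content(tman$content),
                                  tman$version_string, user = user, name = tnm)
    }
    content <- manifest$content
    state <- workflow_from_canonical(normalize_workflow_content(content))
    for (i in seq_along(state$stages)) {
      tl <- state$stages[[i]]$tool
      if (tl %in% names(remap)) state$stages[[i]]$tool <- remap[[tl]]
    }
    nm <- free_name(state$name, registry$workflow_names())
    state$name <- nm
    registry$create_workflow(state, user = user)
    v <- registry$publish_workflow(nm, manifest$version_string, user = user)
    list(kind = "workflow", name = nm, version = v$version_string)
  } else {
    abort("malformed archive: unknown manifest kind")
  }
}

read_text <- function(path) {
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

free_name <- function(name, taken) {
  if (!name %in% taken) return(name)
  i <- 1
  repeat {
    cand <- sprintf("%s (imported-%d)", name, i)
    if (!cand %in% taken) return(cand)
    i <- i + 1
  }
}

# JSON round-trips lose scalar types in places; coerce back to the shapes
# the constructors expect
normalize_tool_content <- function(content) {
  content$scripts <- lapply(content$scripts, as.character)
  content
}

normalize_workflow_content <- function(content) content
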