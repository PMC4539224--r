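#' Working-directory snapshots
#'
#' A snapshot is a full copy of a job's working directory at a moment in
#' time, stored under `<working_dir>/.snapshots/<label>/`.  The engine
#' takes one at the start of every checkpoint stage (that copy is what a
#' later resume restores) and, when `snapshot_sequential` is on, after
#' every sequential stage for the job history.  Restoring a snapshot and
#' archiving again reproduces the identical content digest.
#'
#' @param working_dir job working directory.
#' @param label snapshot name (unique within the job).
#' @return `take_snapshot()` and `restore_snapshot()` return the label /
#'   working directory invisibly; `snapshot_digest()` and
#'   [workdir_digest()] return a SHA-256 hex digest of the directory
#'   content (relative paths + file bytes, snapshot store excluded).
#' @export
take_snapshot <- function(working_dir, label) {
  snap_dir <- file.path(working_dir, ".snapshots", label)
  if (dir.exists(snap_dir)) unlink(snap_dir, recursive = TRUE)
  dir.create(snap_dir, recursive = TRUE)
  for (rel in workdir_files(working_dir)) {
    target <- file.path(snap_dir, rel)
    dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(working_dir, rel), target, copy.mode = TRUE)
  }
  invisible(label)
}

#' @rdname take_snapshot
#' @export
restore_snapshot <- function(working_dir, label) {
  snap_dir <- file.path(working_dir, ".snapshots", label)
  if (!dir.exists(snap_dir)) {
    abort(sprintf("no snapshot '%s' under '%s'", label, working_dir))
  }
  for (rel in workdir_files(working_dir)) {
    unlink(file.path(working_dir, rel))
  }
  # prune now-empty directories, then copy the snapshot back
  dirs <- list.dirs(working_dir, recursive = TRUE, full.names = TRUE)
  dirs <- dirs[!grepl("/\\.snapshots", dirs) & dirs != working_dir]
  unlink(dirs, recursive = TRUE)
  files <- list.files(snap_dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  for (rel in files) {
    target <- file.path(working_dir, rel)
    dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(snap_dir, rel), target, copy.mode = TRUE)
  }
  invisible(working_dir)
}

#' @rdname take_snapshot
#' @export
snapshot_digest <- function(working_dir, label) {
  workdir_digest(file.path(working_dir, ".snapshots", label))
}

#' @rdname take_snapshot
#' @export
workdir_digest <- function(working_dir) {
  rels <- sort(workdir_files(working_dir), method = "radix")
  entries <- vapply(rels, function(rel) {
    path <- file.path(working_dir, rel)
    paste0(rel, ":", as.character(openssl::sha256(readBin(path, "raw", file.size(path)))))
  }, character(1))
  sha256_hex(paste(entries, collapse = "\n"))
}

# all files of a working directory except the snapshot store
workdir_files <- function(working_dir) {
  files <- list.files(working_dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  files[!startsWith(files, ".snapshots/") & files != ".snapshots"]
}
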