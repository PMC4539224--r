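#' Tidy a job run into a stage table
#'
#' @param x a [JobRun].
#' @param ... unused.
#' @return tibble with one row per stage: state, exit status, timestamps,
#'   snapshot refs and stream sizes.
#' @export
tidy.JobRun <- function(x, ...) {
  dplyr::bind_rows(lapply(x$stage_runs, function(s) {
    tibble(
      stage_id = s$stage_id,
      state = s$state,
      exit_status = if (is.null(s$exit_status)) NA_integer_ else s$exit_status,
      started_at = s$started_at %||% as.POSIXct(NA),
      finished_at = s$finished_at %||% as.POSIXct(NA),
      is_checkpoint = !is.null(s$snapshot_ref),
      snapshot_ref = s$snapshot_ref %||% NA_character_,
      carried = isTRUE(s$carried),
      stdout_bytes = if (is.null(s$stdout)) NA_integer_ else nchar(s$stdout, type = "bytes")
    )
  }))
}

#' One-row summary of a job run
#'
#' @param x a [JobRun].
#' @param ... unused.
#' @return one-row tibble: job id, workflow, status, stage-state counts,
#'   wall time.
#' @export
glance.JobRun <- function(x, ...) {
  states <- vapply(x$stage_runs, `[[`, character(1), "state")
  tibble(
    job_id = x$job_id, workflow = x$workflow, version = x$version,
    user = x$user, status = x$status,
    n_stages = length(states),
    n_completed = sum(states == "COMPLETED"),
    n_failed = sum(states == "FAILED"),
    n_skipped = sum(states == "SKIPPED"),
    n_cancelled = sum(states == "CANCELLED"),
    elapsed_s = if (is.null(x$finished_at)) NA_real_ else
      as.numeric(difftime(x$finished_at, x$created_at, units = "secs"))
  )
}

#' @export
print.JobRun <- function(x, ...) {
  cat(sprintf("<JobRun %s> %s@%s by %s: %s\n", x$job_id, x$workflow,
              x$version, x$user, x$status))
  tb <- tidy(x)
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-10s %-10s exit=%s\n", tb$stage_id[i], tb$state[i],
                ifelse(is.na(tb$exit_status[i]), "-", tb$exit_status[i])))
  }
  invisible(x)
}

#' Stage timeline plot for a job run
#'
#' Draws each stage as a horizontal interval from its start to its end,
#' coloured by terminal state — overlapping bars are stages that genuinely
#' ran in parallel.
#'
#' @param object a [JobRun].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.JobRun <- function(object, ...) {
  tb <- tidy(object)
  tb <- tb[!is.na(tb$started_at), , drop = FALSE]
  t0 <- min(tb$started_at)
  tb$start_s <- as.numeric(difftime(tb$started_at, t0, units = "secs"))
  tb$end_s <- as.numeric(difftime(tb$finished_at, t0, units = "secs"))
  ggplot2::ggplot(tb, ggplot2::aes(y = stats::reorder(.data$stage_id, -.data$start_s))) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   yend = stats::reorder(.data$stage_id, -.data$start_s),
                   colour = .data$state),
      linewidth = 4) +
    ggplot2::labs(x = "seconds since first launch", y = NULL,
                  title = sprintf("%s (%s)", object$job_id, object$status)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
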