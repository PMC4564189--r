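# Tabular input/output: trajectory and event CSVs, JSON reports, and run
# manifests.

#' Write / read trajectories as CSV
#'
#' Schema: `molecule_id`, `t_s`, `x_bp`, optional `truth_x_bp` (and
#' `condition` for multi-condition tables).  The same schema is produced by
#' [track_stack()]-derived traces, so simulated and tracked data enter the
#' analysis identically.
#'
#' @param x an `fs_trajectory_set`, a named list of them, or a data frame
#'   already in the schema.
#' @param path CSV path.
#' @return `read_trajectories_csv` returns the data frame, checked against
#'   the schema.
#' @export
write_trajectories_csv <- function(x, path) {
  d <- if (is.data.frame(x)) x else trajectories_df(x)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "t_s", "x_bp")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_trajectories_csv: missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$t_s) | !is.finite(d$x_bp))
  if (length(bad))
    stop("read_trajectories_csv: non-finite values at rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  d
}

#' Write / read detected events as CSV
#'
#' Schema: `molecule_id`, `t_start`, `t_end`, `bases`, `rate`, `pol_class`
#' (plus any extra columns such as `label`, `condition`).
#'
#' @param events segment/event data frame.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "t_start", "t_end", "bases", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_events_csv: missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Serialize an analysis report to JSON
#'
#' @param x a list of results (summaries, tests, fits).
#' @param path output JSON path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run manifest for a pipeline invocation
#'
#' Records what was run, with which seed and configuration, so every report
#' can be traced to its inputs.
#'
#' @param command short description of the step.
#' @param config the configuration object used.
#' @param seed the master seed.
#' @param inputs,outputs character vectors of paths.
#' @return list suitable for [write_report_json()].
#' @export
run_manifest <- function(command, config = NULL, seed = NULL,
                         inputs = character(0), outputs = character(0)) {
  cfg_hash <- if (!is.null(config)) {
    s <- paste(utils::capture.output(utils::str(unclass(config))),
               collapse = "\n")
    sum(utf8ToInt(s) * seq_len(nchar(s, type = "bytes"))) %% 2147483647
  } else NA
  list(command = command,
       config_hash = cfg_hash,
       seed = seed,
       inputs = inputs, outputs = outputs,
       tool_version = as.character(utils::packageVersion("flowstretch")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
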