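TRIAL_TABLE_COLUMNS <- c("session_id", "trial_id", "coherence_pct",
                         "preferred_pool", "choice", "correct",
                         "decision_time_s", "rc", "rc_sum", "rc_absdiff",
                         "rc_totalinput", "seed")

#' Load a run configuration
#'
#' Reads a YAML configuration with optional sections `parameters`
#' (overrides for [model_parameters()]), `protocol` (overrides for
#' [trial_protocol()]), `plan` (overrides for [experiment_plan()]) and
#' top-level keys `output_dir`, `save_traces`, `log_level`. Every
#' unspecified field keeps its default; unknown keys are rejected with the
#' offending key named. An empty (or missing-section) file yields the
#' default configuration.
#'
#' @param path path to a YAML file, or `NULL` for the defaults
#' @return An object of class `run_config`: a list with `params`,
#'   `protocol`, `plan`, `output_dir`, `save_traces`, `log_level`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("parameters:\n  theta: 30", cfg_file)
#' load_config(cfg_file)$params$theta
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw))
      stop("config file must be a YAML mapping", call. = FALSE)
  }
  known_top <- c("parameters", "protocol", "plan", "output_dir",
                 "save_traces", "log_level")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(model_parameters, as.list(raw$parameters))

  proto_over <- as.list(raw$protocol)
  known_proto <- names(formals(trial_protocol))
  unknown <- setdiff(names(proto_over), known_proto)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  protocol <- do.call(trial_protocol, proto_over)

  plan_over <- as.list(raw$plan)
  known_plan <- names(formals(experiment_plan))
  unknown <- setdiff(names(plan_over), known_plan)
  if (length(unknown))
    stop("unknown plan key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  plan <- do.call(experiment_plan, plan_over)

  structure(list(params = params, protocol = protocol, plan = plan,
                 output_dir = if (is.null(raw$output_dir)) "."
                              else as.character(raw$output_dir),
                 save_traces = isTRUE(raw$save_traces),
                 log_level = if (is.null(raw$log_level)) "info"
                             else as.character(raw$log_level)),
            class = "run_config")
}

#' Write the fully resolved configuration
#'
#' Serialises a `run_config` (defaults plus overrides plus master seed) to
#' YAML next to a run's outputs, so the run can be reconstructed exactly
#' from the emitted file.
#'
#' @param config a `run_config` from [load_config()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(parameters = unclass(config$params),
              protocol = unclass(config$protocol),
              plan = Filter(Negate(is.null), unclass(config$plan)),
              output_dir = config$output_dir,
              save_traces = config$save_traces,
              log_level = config$log_level)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a trial table to CSV
#'
#' Fixed schema, UTF-8, `.` decimal separator, missing values as empty
#' fields; one row per trial. Round-trips losslessly through
#' [read_trial_table()].
#'
#' @param table a `trial_table` from [run_experiment()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  miss <- setdiff(TRIAL_TABLE_COLUMNS, names(table))
  if (length(miss))
    stop("trial table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(table[, TRIAL_TABLE_COLUMNS], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path path to a CSV written by [write_trial_table()]
#' @return A `trial_table` data frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path))
    stop("trial table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(TRIAL_TABLE_COLUMNS, names(tab))
  if (length(miss))
    stop("trial table file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab$preferred_pool <- as.character(tab$preferred_pool)
  tab$choice <- as.character(tab$choice)
  tab$correct <- as.logical(tab$correct)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write a sweep result to CSV
#'
#' Long format: one row per (a_0, a_1, coherence) cell with the mean and
#' relative confidence, plus the per-cell coding slope repeated on each of
#' its rows.
#'
#' @param sweep a `sweep_result` from [run_sweep()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  cells <- merge(sweep$cells, sweep$slopes, by = c("a_0", "a_1"),
                 sort = FALSE)
  utils::write.csv(cells, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis summary as CSV and JSON
#'
#' @param summary a data frame produced by one of the analysis functions
#' @param path_csv CSV output path
#' @param path_json optional JSON output path
#' @return `path_csv`, invisibly.
#' @export
write_summary <- function(summary, path_csv, path_json = NULL) {
  utils::write.csv(summary, path_csv, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(path_json))
    jsonlite::write_json(summary, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path_csv)
}
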