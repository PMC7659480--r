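# Plain-text serialization: trace/event CSVs, protocol YAML, result tables.

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
}

# write a data frame with doubles rendered at full (17 significant digit)
# precision so every numeric round-trips bit-identically through read_csv
write_csv_exact <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      x <- df[[nm]]
      df[[nm]] <- ifelse(is.na(x), NA, sprintf("%.17g", x))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

read_csv_base <- function(path, colClasses = NA) {
  tibble::as_tibble(utils::read.csv(path, colClasses = colClasses,
                                    check.names = FALSE))
}

#' Read / write an oxygen trace CSV
#'
#' The trace dialect has header `time_s,o2_um` with optional `chamber_id`
#' and `sample_id` columns (constant per file). Numbers round-trip exactly.
#'
#' @param path File path.
#' @return `read_trace_csv()` returns an [oxygen_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read_csv_base(path)
  require_columns(df, c("time_s", "o2_um"), "trace CSV")
  if (!is.numeric(df$time_s) || !is.numeric(df$o2_um)) {
    abort("trace CSV columns time_s/o2_um must be numeric.")
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    n_bad <- which(diff(df$time_s) <= 0)[1] + 1
    abort(paste0("non-monotonic time in trace CSV at line ", n_bad + 1, "."))
  }
  oxygen_trace(df$time_s, df$o2_um,
               chamber_id = if ("chamber_id" %in% names(df))
                 as.character(df$chamber_id[1]) else "A",
               sample_id = if ("sample_id" %in% names(df))
                 as.character(df$sample_id[1]) else "S1")
}

#' @rdname read_trace_csv
#' @param trace An [oxygen_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  df <- tibble::tibble(
    time_s = trace$time_s, o2_um = trace$o2_um,
    chamber_id = attr(trace, "chamber_id"),
    sample_id = attr(trace, "sample_id")
  )
  write_csv_exact(df, path)
}

#' Read / write a titration-event CSV
#'
#' Header `time_s,reagent,dose,units`.
#'
#' @param path File path.
#' @return `read_events_csv()` returns a [titration_events()] table.
#' @export
read_events_csv <- function(path) {
  df <- read_csv_base(path, colClasses = c(
    time_s = "numeric", reagent = "character",
    dose = "numeric", units = "character"
  ))
  require_columns(df, c("time_s", "reagent"), "event CSV")
  titration_events(df$time_s, df$reagent,
                   dose = if ("dose" %in% names(df)) df$dose else NA_real_,
                   units = if ("units" %in% names(df)) df$units else NA_character_)
}

#' @rdname read_events_csv
#' @param events A [titration_events()] table.
#' @export
write_events_csv <- function(events, path) {
  write_csv_exact(tibble::as_tibble(events), path)
}

#' Read / write a protocol definition as YAML
#'
#' Key-value fields plus the ordered transition list, the format used for
#' user-defined protocols; built-in protocols are addressable by name via
#' [builtin_protocol()].
#'
#' @param path File path.
#' @return `read_protocol()` returns a [protocol_definition()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  protocol_definition(
    name = y$name,
    transitions = tibble::tibble(
      reagent = vapply(y$transitions, `[[`, "", "reagent"),
      state = vapply(y$transitions, `[[`, "", "state")
    ),
    reference_state = y$reference_state %||% "ETS",
    ets_rule = y$ets_rule %||% "max_plateau",
    doses = y$doses %||% list()
  )
}

#' @rdname read_protocol
#' @param protocol A [protocol_definition()].
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(list(
    name = protocol$name,
    reference_state = protocol$reference_state,
    ets_rule = protocol$ets_rule,
    transitions = lapply(seq_len(nrow(protocol$transitions)), function(i) {
      list(reagent = protocol$transitions$reagent[i],
           state = protocol$transitions$state[i])
    }),
    doses = protocol$doses
  ), path)
  invisible(path)
}

#' Serialize / parse a whole run
#'
#' Writes one run as a directory of plain-text artifacts (`trace.csv`,
#' `events.csv`, `protocol.yml`, `meta.yml`); `read_run()` reproduces every
#' field bit-identically.
#'
#' @param run A [run_record()].
#' @param dir Directory to create/populate.
#' @return `read_run()` returns a [run_record()].
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trace_csv(run$trace, file.path(dir, "trace.csv"))
  write_events_csv(run$events, file.path(dir, "events.csv"))
  write_protocol(run$protocol, file.path(dir, "protocol.yml"))
  ch <- run$chamber
  yaml::write_yaml(list(
    group = run$group, temperature = attr(run$trace, "temperature"),
    chamber = list(volume_ml = ch$volume_ml, cell_mio = ch$cell_mio,
                   stir_rpm = ch$stir_rpm, background_a = ch$background_a,
                   background_b = ch$background_b)
  ), file.path(dir, "meta.yml"), precision = 17)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  trace <- read_trace_csv(file.path(dir, "trace.csv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yml"))
  attr(trace, "temperature") <- meta$temperature
  run_record(
    trace = trace,
    events = read_events_csv(file.path(dir, "events.csv")),
    chamber = chamber_config(
      volume_ml = meta$chamber$volume_ml, cell_mio = meta$chamber$cell_mio,
      stir_rpm = meta$chamber$stir_rpm,
      background_a = meta$chamber$background_a,
      background_b = meta$chamber$background_b
    ),
    protocol = read_protocol(file.path(dir, "protocol.yml")),
    group = meta$group
  )
}

#' Read / write result tables
#'
#' Long-format tidy CSVs: the per-state flux table
#' (`sample_id,group,state,raw_flux,rox_corrected_flux,t_start,t_end,sd_flux,n_points`),
#' the metrics table (`sample_id,group,metric,state,value`) and the
#' comparison panel. Every writer's output round-trips through the matching
#' reader.
#'
#' @param table The table to write.
#' @param path File path.
#' @name result_io
#' @export
write_state_fluxes <- function(table, path) {
  write_csv_exact(tibble::as_tibble(table), path)
}

#' @rdname result_io
#' @export
read_state_fluxes <- function(path) {
  df <- read_csv_base(path, colClasses = c(
    sample_id = "character", group = "character", state = "character"
  ))
  require_columns(df, c("sample_id", "group", "state", "raw_flux",
                        "rox_corrected_flux"), "state-flux CSV")
  structure(df, class = c("state_flux_tbl", class(df)))
}

#' @rdname result_io
#' @export
write_metrics <- function(table, path) {
  write_csv_exact(tibble::as_tibble(table), path)
}

#' @rdname result_io
#' @export
read_metrics <- function(path) {
  df <- read_csv_base(path, colClasses = c(
    sample_id = "character", group = "character",
    metric = "character", state = "character"
  ))
  require_columns(df, c("sample_id", "group", "metric", "state", "value"),
                  "metrics CSV")
  structure(df, class = c("metrics_tbl", class(df)))
}

#' @rdname result_io
#' @export
write_comparison <- function(table, path) {
  write_csv_exact(tibble::as_tibble(table), path)
}
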