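#' Write / read a trace as CSV with a JSON sidecar
#'
#' The CSV has columns `time_ms`, `value`; the sidecar (`<path>.json`)
#' records units, sampling, site and any seed, so a trace round-trips
#' losslessly up to numeric-text precision.
#'
#' @param record a [trace_record()].
#' @param path CSV file path.
#' @param seed optional seed recorded in the sidecar.
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(record, path, seed = NULL, extra = NULL) {
  stopifnot(inherits(record, "trace_record"))
  df <- as.data.frame(record)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  units <- c(voltage = "mV", current = "nA", conductance = "uS")
  side <- c(list(kind = record$kind, units = unname(units[record$kind]),
                 dt_ms = record$dt, t0_ms = record$t0, site = record$site,
                 n_samples = length(record$samples), seed = seed), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  sidefile <- paste0(path, ".json")
  if (file.exists(sidefile)) {
    side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
    trace_record(df$value, side$dt_ms, side$t0_ms, side$kind, side$site)
  } else {
    dt <- median(diff(df$time_ms))
    trace_record(df$value, dt, df$time_ms[1])
  }
}

#' Write / read an I-V curve as CSV
#'
#' @param curve an [iv_curve()].
#' @param path CSV path (columns `v_mV`, `i_nA`).
#' @return `path` / an [iv_curve()].
#' @export
write_iv <- function(curve, path) {
  stopifnot(inherits(curve, "iv_curve"))
  utils::write.csv(data.frame(v_mV = curve$v, i_nA = curve$i), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(condition = attr(curve, "condition"),
                            duration_ms = attr(curve, "duration_ms")),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_iv
#' @export
read_iv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  dur <- NA_real_; cond <- ""
  if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(s$duration_ms)) dur <- s$duration_ms
    if (!is.null(s$condition)) cond <- s$condition
  }
  iv_curve(df$v_mV, df$i_nA, condition = cond, duration_ms = dur)
}

#' Write / read an event series as CSV
#'
#' @param events an [event_series()].
#' @param path CSV path (columns `time_ms`[, `amplitude`]).
#' @return `path` / an [event_series()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_series"))
  df <- data.frame(time_ms = events$times)
  if (!is.null(events$amplitudes)) df$amplitude <- events$amplitudes
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  event_series(df$time_ms, df$amplitude, method = "file")
}

#' Write a run manifest
#'
#' Records what a protocol run produced: output files, seeds, a hash of
#' the configuration, package version and timestamp.  Written even when a
#' protocol fails partway, so runs are always traceable.
#'
#' @param path manifest JSON path.
#' @param outputs character vector of output file paths.
#' @param seeds integer seeds used.
#' @param config named list of configuration values (hashed).
#' @param status `"ok"` or an error description.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, outputs = character(0),
                           seeds = integer(0), config = list(),
                           status = "ok") {
  cfg_str <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  man <- list(
    package = "fsikir",
    version = as.character(utils::packageVersion("fsikir")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        seq_along(utf8ToInt(cfg_str))) %%
                            .Machine$integer.max),
    seeds = seeds, outputs = outputs, status = status)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(man)
}
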