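# Plain-text I/O: spike/interval/event tables as CSV, statistics as JSON,
# pipeline configuration as YAML.

#' Write and read spike-event tables
#'
#' CSV with header `channel,time_s,amplitude_uv`.
#'
#' @param spikes A [spike_events()] table.
#' @param path File path.
#' @return `write_spike_events()` returns `path` invisibly;
#'   `read_spike_events()` returns a [spike_events()] table.
#' @export
write_spike_events <- function(spikes, path) {
  write.csv(as.data.frame(spikes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  df <- read.csv(path)
  spike_events(df$channel, df$time_s, df$amplitude_uv)
}

#' Write and read interval sets
#'
#' CSV with header `label,start_s,end_s,n_spikes,n_sub_bursts`.
#'
#' @param intervals An [interval_set()].
#' @param path File path.
#' @return `write_intervals()` returns `path` invisibly; `read_intervals()`
#'   an [interval_set()].
#' @export
write_intervals <- function(intervals, path) {
  df <- data.frame(label = intervals$label, start_s = intervals$start,
                   end_s = intervals$end, n_spikes = intervals$n_spikes,
                   n_sub_bursts = intervals$n_sub_bursts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  df <- read.csv(path)
  interval_set(df$label, df$start_s, df$end_s, df$n_spikes, df$n_sub_bursts)
}

#' Write and read fluorescence traces
#'
#' Long CSV with header `cell_id,cell_type,t_s,F`.
#'
#' @param traces List of [fluorescence_trace()]s.
#' @param path File path.
#' @param sampling_rate Frame rate assumed by `read_traces()` when
#'   reconstructing traces (default: inferred from the time column).
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a list
#'   of [fluorescence_trace()]s.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, cell_type = tr$cell_type,
               t_s = trace_times(tr), F = tr$values)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, sampling_rate = NULL) {
  df <- read.csv(path)
  lapply(split(df, df$cell_id), function(d) {
    fs <- sampling_rate %||%
      (1 / stats::median(diff(d$t_s)))
    fluorescence_trace(d$F, fs, d$cell_id[1], d$cell_type[1])
  })
}

#' Write a statistics list to JSON
#'
#' @param stats A list or data.frame of summary statistics.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  # strip S3 classes (burst_stats, ca_events, ...) so jsonlite serializes
  # the underlying list/data.frame
  if (is.data.frame(stats)) {
    class(stats) <- "data.frame"
  } else if (is.list(stats)) {
    stats <- unclass(stats)
  }
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
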